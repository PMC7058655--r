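# Patient-level bootstrap for broken-stick fits.
#
# The resampling unit is the patient: a replicate redraws n patients with
# replacement, rebuilds the pooled daily-mean series from their specimens,
# and refits the broken stick. Replicate multiplicities are drawn as one
# multinomial vector per replicate, so daily sums/counts reduce to matrix
# products of per-patient day matrices -- the whole replicate set is fitted
# in a handful of matrix operations.

# per-patient x day sum and count matrices for one biomarker
pd_matrices <- function(m, ids) {
  days <- sort(unique(m$day))
  pf <- factor(m$patient_id, levels = ids)
  df <- factor(m$day, levels = days)
  N <- as.matrix(table(pf, df))
  S <- tapply(m$value, list(pf, df), sum)
  S[is.na(S)] <- 0
  list(S = unname(S), N = unname(N), days = days, ids = ids)
}

# fit every column of Y (days x replicates, NaN for absent days) on the
# shared candidate grid; returns replicates x 4 matrix, NA rows = failures
bsr_fit_multi <- function(days, Y, c_search, grid_step) {
  R <- ncol(Y)
  est <- matrix(NA_real_, R, 4,
                dimnames = list(NULL, c("c", "level_at_c", "slope_pre", "slope_post")))
  complete <- colSums(!is.finite(Y)) == 0L
  grid <- bsr_c_grid(days, c_search, grid_step)
  if (any(complete) && length(grid)) {
    # orthogonal-basis closed form (see bsr_profile), vectorised over both
    # candidates and replicates
    Yok <- Y[, complete, drop = FALSE]
    D <- outer(days, grid, "-")
    X1 <- pmin(D, 0); X2 <- pmax(D, 0)
    n <- length(days)
    s1 <- colSums(X1); s2 <- colSums(X2)
    q1 <- colSums(X1^2); q2 <- colSums(X2^2)
    den <- n - s1^2 / q1 - s2^2 / q2
    B0 <- colSums(Yok)                       # replicates
    B1 <- crossprod(X1, Yok); B2 <- crossprod(X2, Yok)  # candidates x reps
    BETA0 <- (outer(rep(1, length(grid)), B0) - (s1 / q1) * B1 -
                (s2 / q2) * B2) / den
    BETA1 <- (B1 - s1 * BETA0) / q1
    BETA2 <- (B2 - s2 * BETA0) / q2
    SSE <- outer(rep(1, length(grid)), colSums(Yok^2)) -
      (BETA0 * rep(B0, each = length(grid)) + BETA1 * B1 + BETA2 * B2)
    SSE[!is.finite(SSE)] <- Inf
    sub <- matrix(NA_real_, ncol(Yok), 4)
    for (j in seq_len(ncol(Yok))) {
      prof <- SSE[, j]
      if (all(!is.finite(prof))) next
      pick <- bsr_pick(grid, prof)
      i <- pick$index
      sub[j, ] <- c(pick$c, BETA0[i, j], BETA1[i, j], BETA2[i, j])
    }
    est[complete, ] <- sub
  }
  for (j in which(!complete)) {
    pres <- is.finite(Y[, j])
    d <- days[pres]; y <- Y[pres, j]
    if (length(unique(d)) < 4L) next
    cs <- c(max(c_search[1], min(d)), min(c_search[2], max(d)))
    if (cs[1] >= cs[2]) next
    g <- bsr_c_grid(d, cs, grid_step)
    if (!length(g)) next
    w <- rep(1, length(y))
    prof <- bsr_profile(d, y, w, g)
    if (all(!is.finite(prof))) next
    pick <- bsr_pick(g, prof)
    sol <- bsr_solve(d, y, w, pick$c)
    est[j, ] <- c(pick$c, sol$beta)
  }
  est
}

# replicate parameter estimates for one patient set; uses the current RNG
boot_estimates <- function(m, ids, n_reps, c_search, grid_step) {
  pd <- pd_matrices(m, ids)
  np <- length(ids)
  W <- stats::rmultinom(n_reps, np, rep(1 / np, np))   # patients x reps
  Scol <- crossprod(pd$S, W)                           # days x reps
  Ncol <- crossprod(pd$N, W)
  Y <- Scol / Ncol                                     # NaN where count 0
  bsr_fit_multi(pd$days, Y, c_search, grid_step)
}

#' Bootstrap confidence intervals for a broken-stick fit
#'
#' Fits the broken stick to the pooled daily means of one biomarker, then
#' resamples patients with replacement `n_reps` times, rebuilding the daily
#' means and refitting each replicate. Confidence intervals are the 2.5th
#' and 97.5th percentiles of the replicate parameter distributions
#' (percentile bootstrap). Replicates where the fit fails (for example a
#' resample leaving too few distinct days) are excluded from the
#' percentiles and counted.
#'
#' @param measurements measurement data frame (windowed, CRP already
#'   LOD-imputed).
#' @param biomarker `"CRP"` or `"PA"`.
#' @param patient_ids patients to bootstrap over; default the eligible
#'   cohort from [select_cohort()].
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param c_search,grid_step change-point search settings, as in [bsr()].
#' @param level confidence level (default 0.95).
#' @return an object of class `"bsr_boot"`: the full-data `"bsr"` fit plus
#'   `ci` (4 x 2 matrix over all parameters), `replicates` (`n_reps` x 4,
#'   failed rows `NA`), `n_failed`, `n_reps`, `seed`.
#' @export
bsr_boot <- function(measurements, biomarker = c("CRP", "PA"),
                     patient_ids = NULL, n_reps = 1000, seed = 1,
                     c_search = c(-29, 0), grid_step = 0.1, level = 0.95) {
  biomarker <- match.arg(biomarker)
  stopifnot(n_reps >= 1)
  if (is.null(patient_ids)) patient_ids <- select_cohort(measurements, biomarker)
  if (length(patient_ids) == 0L) stop("empty eligible cohort for ", biomarker)
  m <- measurements[measurements$biomarker == biomarker &
                      measurements$patient_id %in% patient_ids, , drop = FALSE]
  dm <- daily_means(m, biomarker)
  fit <- bsr(value ~ day, dm, c_search = c_search, grid_step = grid_step)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  est <- boot_estimates(m, patient_ids, n_reps, c_search, grid_step)

  okrow <- stats::complete.cases(est)
  n_failed <- sum(!okrow)
  if (n_failed > n_reps / 2)
    stop("bootstrap inference failed: ", n_failed, " of ", n_reps,
         " replicates could not be fitted")
  a <- (1 - level) / 2
  ci <- t(apply(est[okrow, , drop = FALSE], 2, stats::quantile, probs = c(a, 1 - a)))
  out <- list(fit = fit, ci = ci, replicates = est, n_failed = n_failed,
              n_reps = n_reps, seed = as.integer(seed), level = level,
              biomarker = biomarker, n_patients = length(patient_ids))
  class(out) <- "bsr_boot"
  out
}

#' @export
print.bsr_boot <- function(x, digits = 3, ...) {
  cat("Broken-stick fit with patient-bootstrap CIs (", x$biomarker, ", ",
      x$n_patients, " patients, ", x$n_reps, " replicates, ",
      x$n_failed, " failed)\n", sep = "")
  tab <- cbind(estimate = coef(x$fit), x$ci)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.bsr_boot <- function(object, ...) coef(object$fit)

#' @export
confint.bsr_boot <- function(object, parm, level, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# eligible patient ids of one microbial group
group_ids <- function(measurements, patients, biomarker, group) {
  elig <- select_cohort(measurements, biomarker)
  intersect(elig, patients$patient_id[patients$group == group])
}

#' Bootstrap difference of a broken-stick parameter between two groups
#'
#' Compares a broken-stick parameter (change-point or one of the segment
#' slopes) between two microbial groups. Each replicate independently
#' resamples each group's eligible patients with replacement, rebuilds the
#' group's daily means, refits the broken stick and records the parameter
#' difference (group a minus group b). The 95% interval is the percentile
#' interval of the replicate differences, and the difference is declared
#' significant when the interval excludes zero.
#'
#' Each group's resampling stream is tied to the group label (streams are
#' drawn in sorted label order), so swapping `group_a` and `group_b`
#' exactly negates every replicate difference. Comparing a group with
#' itself reuses one stream and yields all-zero differences.
#'
#' @param measurements measurement data frame (windowed, CRP LOD-imputed).
#' @param patients patient table (`patient_id`, `group`).
#' @param biomarker `"CRP"` or `"PA"`.
#' @param group_a,group_b group labels present in `patients$group`.
#' @param parameter `"c"`, `"slope_pre"` or `"slope_post"`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param c_search,grid_step change-point search settings.
#' @return an object of class `"bsr_boot_diff"`: `parameter`, `group_a`,
#'   `group_b`, `estimate` (full-data difference), `samples` (successful
#'   replicate differences), `ci95`, `significant`, `n_failed`, `n_reps`,
#'   and `all` (the same summary for all four parameters).
#' @export
bsr_group_diff <- function(measurements, patients, biomarker = c("CRP", "PA"),
                           group_a, group_b,
                           parameter = c("c", "slope_pre", "slope_post"),
                           n_reps = 1000, seed = 1,
                           c_search = c(-29, 0), grid_step = 0.1) {
  biomarker <- match.arg(biomarker)
  parameter <- match.arg(parameter)
  labels <- sort(unique(c(group_a, group_b)))
  ids <- lapply(labels, function(g) group_ids(measurements, patients, biomarker, g))
  names(ids) <- labels

  fits <- list(); mlist <- list()
  for (g in labels) {
    if (length(ids[[g]]) < 4L)
      stop("too few eligible patients in group '", g, "' for robust computation")
    mg <- measurements[measurements$biomarker == biomarker &
                         measurements$patient_id %in% ids[[g]], , drop = FALSE]
    mlist[[g]] <- mg
    fits[[g]] <- tryCatch(
      bsr(value ~ day, daily_means(mg, biomarker),
          c_search = c_search, grid_step = grid_step),
      error = function(e) stop("broken-stick fit failed in group '", g, "': ",
                               conditionMessage(e), call. = FALSE))
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  est <- lapply(labels, function(g)
    boot_estimates(mlist[[g]], ids[[g]], n_reps, c_search, grid_step))
  names(est) <- labels

  D <- est[[group_a]] - est[[group_b]]
  okrow <- stats::complete.cases(D)
  n_failed <- sum(!okrow)
  if (n_failed > n_reps / 2)
    stop("bootstrap inference failed: ", n_failed, " of ", n_reps,
         " replicates could not be fitted")
  Dok <- D[okrow, , drop = FALSE]
  ci_all <- t(apply(Dok, 2, stats::quantile, probs = c(0.025, 0.975)))
  all_tab <- data.frame(parameter = rownames(ci_all),
                        estimate = coef(fits[[group_a]]) - coef(fits[[group_b]]),
                        lower = ci_all[, 1], upper = ci_all[, 2],
                        significant = ci_all[, 1] > 0 | ci_all[, 2] < 0,
                        row.names = NULL)
  out <- list(parameter = parameter, group_a = group_a, group_b = group_b,
              biomarker = biomarker,
              estimate = unname(coef(fits[[group_a]])[parameter] -
                                  coef(fits[[group_b]])[parameter]),
              samples = Dok[, parameter],
              ci95 = unname(ci_all[parameter, ]),
              significant = unname(ci_all[parameter, 1] > 0 | ci_all[parameter, 2] < 0),
              n_failed = n_failed, n_reps = n_reps, seed = as.integer(seed),
              all = all_tab, fits = fits)
  class(out) <- "bsr_boot_diff"
  out
}

#' Bootstrap comparison of a broken-stick parameter against a reference value
#'
#' Resamples one group's (or the whole cohort's) patients, refits, and forms
#' the replicate distribution of `parameter - reference_value`; used, for
#' instance, to test whether a group's change-point differs from day 0.
#'
#' @inheritParams bsr_group_diff
#' @param group group label, or `NULL` for the whole eligible cohort.
#' @param reference_value the fixed value subtracted (default 0).
#' @return a `"bsr_boot_diff"` object; `group_b` records the reference.
#' @export
bsr_vs_reference <- function(measurements, patients = NULL,
                             biomarker = c("CRP", "PA"), group = NULL,
                             parameter = c("c", "slope_pre", "slope_post"),
                             reference_value = 0, n_reps = 1000, seed = 1,
                             c_search = c(-29, 0), grid_step = 0.1) {
  biomarker <- match.arg(biomarker)
  parameter <- match.arg(parameter)
  ids <- if (is.null(group)) select_cohort(measurements, biomarker)
         else group_ids(measurements, patients, biomarker, group)
  if (length(ids) < 4L)
    stop("too few eligible patients in group '",
         if (is.null(group)) "all" else group, "' for robust computation")
  m <- measurements[measurements$biomarker == biomarker &
                      measurements$patient_id %in% ids, , drop = FALSE]
  fit <- bsr(value ~ day, daily_means(m, biomarker),
             c_search = c_search, grid_step = grid_step)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  est <- boot_estimates(m, ids, n_reps, c_search, grid_step)

  ref <- c(0, 0, 0, 0)
  names(ref) <- colnames(est)
  ref[parameter] <- reference_value
  D <- sweep(est, 2, ref)
  okrow <- stats::complete.cases(D)
  n_failed <- sum(!okrow)
  if (n_failed > n_reps / 2)
    stop("bootstrap inference failed: ", n_failed, " of ", n_reps,
         " replicates could not be fitted")
  Dok <- D[okrow, , drop = FALSE]
  ci <- stats::quantile(Dok[, parameter], c(0.025, 0.975))
  out <- list(parameter = parameter,
              group_a = if (is.null(group)) "all" else group,
              group_b = sprintf("reference=%g", reference_value),
              biomarker = biomarker,
              estimate = unname(coef(fit)[parameter]) - reference_value,
              samples = Dok[, parameter],
              ci95 = unname(ci),
              significant = unname(ci[1] > 0 | ci[2] < 0),
              n_failed = n_failed, n_reps = n_reps, seed = as.integer(seed),
              all = NULL, fits = list(fit))
  class(out) <- "bsr_boot_diff"
  out
}

#' @export
print.bsr_boot_diff <- function(x, digits = 3, ...) {
  cat("Bootstrap parameter difference (", x$biomarker, "): ",
      x$parameter, ", ", x$group_a, " - ", x$group_b, "\n", sep = "")
  cat("  estimate:", format(x$estimate, digits = digits),
      "  95% CI: [", format(x$ci95[1], digits = digits), ",",
      format(x$ci95[2], digits = digits), "]",
      if (x$significant) " *significant*" else " (not significant)", "\n")
  cat("  replicates:", x$n_reps, " failed:", x$n_failed, "\n")
  invisible(x)
}
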