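#' Generate a synthetic CA-BSI cohort
#'
#' Draws a cohort from a scenario: each patient gets a microbial group from
#' the group mixture; on each day from -30 to 1, each biomarker is measured
#' with the day's sampling probability (independent Bernoulli per patient,
#' day and biomarker); a measured value is the group's piecewise-linear mean
#' at that day plus noise — multiplicative log-normal for CRP (right-skewed)
#' and additive normal for PA (symmetric). Negative draws are truncated at
#' zero. CRP values below the limit of detection are emitted flagged
#' `below_lod` with the value coded as the LOD itself (the unquantified
#' "<LOD" laboratory code); [impute_below_lod()] turns them into analysable
#' values. PA values below the implausibility floor are emitted unflagged so
#' that [exclude_implausible_pa()] has something to remove.
#'
#' The generator is a pure function of `(scenario, seed)`.
#'
#' @param scenario a validated [bsi_scenario()].
#' @param seed integer seed; same scenario and seed give an identical cohort.
#' @return an object of class `"bsi_cohort"`: a list with
#'   `measurements` (data frame `patient_id`, `biomarker`, `day`, `value`,
#'   `below_lod`) and `patients` (data frame `patient_id`, `group`), plus the
#'   scenario and seed as attributes.
#' @examples
#' coh <- simulate_cohort(default_paper_scenario(50), seed = 1)
#' head(coh$measurements)
#' table(coh$patients$group)
#' @export
simulate_cohort <- function(scenario, seed) {
  validate_scenario(scenario)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- scenario
  n <- as.integer(s$n_patients)
  days <- bsi_days
  nd <- length(days)
  prob <- unname(s$sampling_profile[as.character(days)])

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  pid <- sprintf("P%04d", seq_len(n))
  group <- sample(bsi_groups, n, replace = TRUE, prob = s$group_probs[bsi_groups])

  meas <- vector("list", 2L)
  for (bi in seq_along(bsi_biomarkers)) {
    b <- bsi_biomarkers[bi]
    # n x nd matrices; patients in rows, days in columns
    sampled <- matrix(stats::runif(n * nd) < rep(prob, each = n), n, nd)
    gm <- t(vapply(bsi_groups, function(g) kinetics_mean(s$kinetics[[g]][[b]], days),
                   numeric(nd)))
    mu <- gm[match(group, bsi_groups), , drop = FALSE]
    ri_sd <- s$patient_intercept_sd[[b]]
    if (ri_sd > 0) mu <- mu + stats::rnorm(n, 0, ri_sd)
    if (b == "CRP") {
      val <- mu * exp(matrix(stats::rnorm(n * nd, 0, s$crp_noise_sd_log), n, nd))
    } else {
      val <- mu + matrix(stats::rnorm(n * nd, 0, s$pa_noise_sd), n, nd)
    }
    val <- pmax(val, 0)  # concentrations are physical quantities
    idx <- which(sampled)
    df <- data.frame(patient_id = pid[row(sampled)[idx]],
                     biomarker = b,
                     day = days[col(sampled)[idx]],
                     value = val[idx],
                     below_lod = FALSE,
                     stringsAsFactors = FALSE)
    if (b == "CRP") {
      cens <- df$value < s$crp_lod
      df$below_lod[cens] <- TRUE
      df$value[cens] <- s$crp_lod
    }
    meas[[bi]] <- df
  }
  measurements <- do.call(rbind, meas)
  measurements <- measurements[order(measurements$patient_id, measurements$biomarker,
                                     measurements$day), , drop = FALSE]
  rownames(measurements) <- NULL

  out <- list(measurements = measurements,
              patients = data.frame(patient_id = pid, group = group,
                                    stringsAsFactors = FALSE))
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- as.integer(seed)
  class(out) <- "bsi_cohort"
  out
}

#' @export
print.bsi_cohort <- function(x, ...) {
  cat("Synthetic CA-BSI cohort:", nrow(x$patients), "patients,",
      nrow(x$measurements), "measurements\n")
  print(table(x$patients$group))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' The on-disk form is the pipeline's long measurement table
#' (`patient_id, biomarker, day, value, below_lod`) and a patient table
#' (`patient_id, group`), both CSV with a header row.
#'
#' @param cohort a `"bsi_cohort"` (or a list with `measurements` and
#'   `patients` data frames).
#' @param measurements_path,patients_path output file paths.
#' @return `write_cohort()`: invisibly, the two paths; `read_cohort()`: a
#'   `"bsi_cohort"` list.
#' @export
write_cohort <- function(cohort, measurements_path, patients_path) {
  utils::write.csv(cohort$measurements, measurements_path, row.names = FALSE)
  utils::write.csv(cohort$patients, patients_path, row.names = FALSE)
  invisible(c(measurements_path, patients_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(measurements_path, patients_path) {
  m <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  p <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "biomarker", "day", "value", "below_lod")
  if (!all(need %in% names(m)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  if (!all(c("patient_id", "group") %in% names(p)))
    stop("patient table must have columns: patient_id, group")
  m$below_lod <- as.logical(m$below_lod)
  structure(list(measurements = m, patients = p), class = "bsi_cohort")
}
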