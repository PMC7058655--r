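#' Default early/late slope windows
#'
#' The early window ends where the cohort-level change-point analysis puts
#' the last whole day before the change (day -4 for CRP, day -2 for PA);
#' the late window runs from the next day through day 1.
#'
#' @param biomarker `"CRP"` or `"PA"`.
#' @return list with `early` and `late` length-2 integer windows.
#' @export
default_slope_windows <- function(biomarker = c("CRP", "PA")) {
  biomarker <- match.arg(biomarker)
  if (biomarker == "CRP") list(early = c(-30, -4), late = c(-3, 1))
  else list(early = c(-30, -2), late = c(-1, 1))
}

#' Per-patient early/late slopes
#'
#' For every eligible patient with at least two specimens in each of two
#' fixed windows (and at least two distinct days per window, so a slope is
#' defined), fits an ordinary least-squares line of value on day within
#' each window using only that patient's specimens, and reports the two
#' slopes. Same-day duplicate specimens both enter the regression.
#' Excluded patients are reported with a reason in attribute `exclusions`.
#'
#' @param measurements measurement data frame (windowed, CRP LOD-imputed).
#' @param patients optional patient table to carry the microbial group.
#' @param biomarker `"CRP"` or `"PA"`.
#' @param window_early,window_late length-2 inclusive day windows; defaults
#'   from [default_slope_windows()]. Must be disjoint and within [-30, 1].
#' @return data frame (class `"slope_pairs"`) with one row per included
#'   patient: `patient_id`, `biomarker`, `slope_early`, `slope_late`,
#'   `n_early`, `n_late`, `group`. Attributes: `exclusions` (data frame
#'   `patient_id`, `reason`), `windows`.
#' @examples
#' m <- data.frame(patient_id = "p1", biomarker = "CRP",
#'                 day = c(-10, -5, -2, 0), value = c(50, 40, 80, 200),
#'                 below_lod = FALSE)
#' slope_pairs(m)  # early slope -2, late slope 60
#' @export
slope_pairs <- function(measurements, patients = NULL,
                        biomarker = c("CRP", "PA"),
                        window_early = NULL, window_late = NULL) {
  biomarker <- match.arg(biomarker)
  w <- default_slope_windows(biomarker)
  if (is.null(window_early)) window_early <- w$early
  if (is.null(window_late)) window_late <- w$late
  stopifnot(length(window_early) == 2L, length(window_late) == 2L,
            window_early[1] <= window_early[2], window_late[1] <= window_late[2])
  if (window_early[2] >= window_late[1] && window_late[2] >= window_early[1])
    stop("slope windows must be disjoint")
  if (min(window_early, window_late) < -30 || max(window_early, window_late) > 1)
    stop("slope windows must lie within [-30, 1]")

  ids <- select_cohort(measurements, biomarker)
  m <- measurements[measurements$biomarker == biomarker &
                      measurements$patient_id %in% ids, , drop = FALSE]
  ols_slope <- function(d, v) {
    dc <- d - mean(d)
    sum(dc * (v - mean(v))) / sum(dc^2)
  }
  rows <- vector("list", length(ids))
  excl <- character(0); excl_id <- character(0)
  for (i in seq_along(ids)) {
    p <- ids[i]
    mp <- m[m$patient_id == p, , drop = FALSE]
    e <- mp[mp$day >= window_early[1] & mp$day <= window_early[2], , drop = FALSE]
    l <- mp[mp$day >= window_late[1] & mp$day <= window_late[2], , drop = FALSE]
    reason <- if (nrow(e) < 2L) "insufficient early specimens"
    else if (nrow(l) < 2L) "insufficient late specimens"
    else if (length(unique(e$day)) < 2L) "single-day early window"
    else if (length(unique(l$day)) < 2L) "single-day late window"
    else NA_character_
    if (!is.na(reason)) {
      excl <- c(excl, reason); excl_id <- c(excl_id, p)
      next
    }
    rows[[i]] <- data.frame(patient_id = p, biomarker = biomarker,
                            slope_early = ols_slope(e$day, e$value),
                            slope_late = ols_slope(l$day, l$value),
                            n_early = nrow(e), n_late = nrow(l),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(), biomarker = character(),
                      slope_early = numeric(), slope_late = numeric(),
                      n_early = integer(), n_late = integer(),
                      stringsAsFactors = FALSE)
  out$group <- if (!is.null(patients))
    patients$group[match(out$patient_id, patients$patient_id)]
  else rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(patient_id = excl_id, reason = excl,
                                        stringsAsFactors = FALSE)
  attr(out, "windows") <- list(early = window_early, late = window_late)
  class(out) <- c("slope_pairs", "data.frame")
  out
}

#' Summarise individual slope patterns
#'
#' The scatter-plot summary of the per-patient slopes: the proportion of
#' patients whose late-window slope moves in the direction expected at
#' infection onset — rising for CRP (a positive acute-phase protein),
#' falling for plasma albumin (a negative one) — plus quartiles of both
#' slopes, overall and by microbial group.
#'
#' @param pairs a [slope_pairs()] result.
#' @param biomarker `"CRP"` or `"PA"`; default taken from `pairs`.
#' @param threshold magnitude a late slope must exceed to count (default 0:
#'   strict sign, `slope_late > 0` for CRP, `slope_late < 0` for PA).
#' @return list with `n`, `proportion`, `direction`, `threshold`, and
#'   `quartiles` (list of matrices for early and late slopes, one row per
#'   group plus `"all"`).
#' @export
summarize_slope_patterns <- function(pairs, biomarker = NULL, threshold = 0) {
  if (is.null(biomarker)) biomarker <- pairs$biomarker[1]
  stopifnot(nrow(pairs) > 0, threshold >= 0)
  if (biomarker == "CRP") {
    hit <- pairs$slope_late > threshold
    direction <- "late-window increase"
  } else {
    hit <- pairs$slope_late < -threshold
    direction <- "late-window decrease"
  }
  qt <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75))
  grp <- if (all(is.na(pairs$group))) rep("all", nrow(pairs)) else pairs$group
  by_group <- function(v) {
    m <- do.call(rbind, lapply(split(v, grp), qt))
    rbind(m, all = qt(v))
  }
  list(n = nrow(pairs),
       proportion = mean(hit),
       direction = direction,
       threshold = threshold,
       quartiles = list(early = by_group(pairs$slope_early),
                        late = by_group(pairs$slope_late)))
}

#' Scatter plot of individual slopes
#'
#' Early-window slope against late-window slope, one point per patient,
#' plotting symbol by microbial group.
#'
#' @param x a [slope_pairs()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.slope_pairs <- function(x, ...) {
  grp <- factor(ifelse(is.na(x$group), "unknown", x$group))
  pch <- c(16, 17, 1, 4)[as.integer(grp)]
  graphics::plot(x$slope_early, x$slope_late,
                 pch = pch,
                 xlab = "early-window slope (units/day)",
                 ylab = "late-window slope (units/day)", ...)
  graphics::abline(h = 0, v = 0, col = "grey60", lty = 2)
  graphics::legend("topleft", legend = levels(grp),
                   pch = c(16, 17, 1, 4)[seq_along(levels(grp))], bty = "n")
  invisible(x)
}
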