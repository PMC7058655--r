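#' Relative-day indexing
#'
#' Whole-day difference between a specimen date and the index (blood
#' culture) date. Day 0 is the day the blood culture is drawn; negative
#' days precede it. There is no time-of-day component.
#'
#' @param specimen_date,index_date `Date` vectors (or strings coercible by
#'   [as.Date()]); recycled to a common length.
#' @return integer vector of relative days.
#' @examples
#' assign_relative_day("2004-03-07", "2004-03-10")  # -3
#' @export
assign_relative_day <- function(specimen_date, index_date) {
  sd <- as.Date(specimen_date)
  id <- as.Date(index_date)
  if (anyNA(sd) || anyNA(id)) stop("dates must be valid")
  as.integer(sd - id)
}

#' Restrict measurements to the analysis window
#'
#' Keeps only measurements with relative day inside `window` (inclusive).
#'
#' @param measurements measurement data frame with a `day` column.
#' @param window length-2 integer window, default `c(-30, 1)`.
#' @return the windowed data frame.
#' @export
window_measurements <- function(measurements, window = c(-30, 1)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  measurements[measurements$day >= window[1] & measurements$day <= window[2], ,
               drop = FALSE]
}

#' Impute CRP values below the limit of detection
#'
#' Laboratory CRP results below the limit of detection (LOD, 10 mg/l) are
#' reported only as "below the limit". Each flagged value is replaced by an
#' independent draw from the uniform distribution on 0-9 mg/l — by default
#' the discrete uniform on the integers \{0, 1, ..., 9\} (CRP is reported in
#' whole mg/l at this scale), optionally the continuous uniform on
#' [0, lod). Unflagged values pass through untouched. Draws come from the
#' session RNG, so set a seed for reproducibility.
#'
#' @param measurements CRP measurement data frame (columns `biomarker`,
#'   `value`, `below_lod`). Passing any non-CRP rows is an error: no LOD
#'   rule exists for plasma albumin.
#' @param lod limit of detection in mg/l (default 10).
#' @param method `"discrete"` (integers 0..lod-1) or `"continuous"`
#'   (uniform on [0, lod)).
#' @return the data frame with flagged values imputed and `below_lod`
#'   retained as a record of which values were imputed.
#' @examples
#' m <- data.frame(patient_id = "a", biomarker = "CRP", day = -2,
#'                 value = c(10, 57), below_lod = c(TRUE, FALSE))
#' set.seed(1)
#' impute_below_lod(m)$value  # first in 0..9, second still 57
#' @export
impute_below_lod <- function(measurements, lod = 10,
                             method = c("discrete", "continuous")) {
  method <- match.arg(method)
  if (any(measurements$biomarker != "CRP"))
    stop("impute_below_lod applies to CRP only; no LOD rule exists for PA")
  flagged <- which(measurements$below_lod)
  if (length(flagged)) {
    measurements$value[flagged] <- switch(
      method,
      discrete = sample(0:(ceiling(lod) - 1), length(flagged), replace = TRUE),
      continuous = stats::runif(length(flagged), 0, lod))
  }
  measurements
}

#' Exclude implausibly low plasma albumin values
#'
#' Removes PA measurements strictly below the floor (default 11 g/l),
#' treated as physiologically unrealistic recording artefacts. The number
#' removed is attached as attribute `n_excluded`.
#'
#' @param measurements PA measurement data frame (column `value`).
#' @param floor exclusion threshold in g/l; values `>= floor` are kept.
#' @return the filtered data frame with attribute `n_excluded`.
#' @examples
#' m <- data.frame(value = c(10.9, 11, 28))
#' exclude_implausible_pa(m)$value  # 11 and 28 survive
#' @export
exclude_implausible_pa <- function(measurements, floor = 11) {
  drop <- measurements$value < floor
  out <- measurements[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Cohort eligibility for one biomarker
#'
#' A patient is eligible for a biomarker's analysis when they have at least
#' one measurement of that biomarker on days -30..-1 AND at least one on
#' day 0 or 1. Eligibility is evaluated per biomarker; a patient can be
#' eligible for CRP, PA, both, or neither.
#'
#' @param measurements measurement data frame (columns `patient_id`,
#'   `biomarker`, `day`), already windowed to -30..1.
#' @param biomarker `"CRP"` or `"PA"`.
#' @return character vector of eligible patient ids (sorted, unique).
#' @seealso [eligible_both()], [cohort_flow_report()]
#' @export
select_cohort <- function(measurements, biomarker = c("CRP", "PA")) {
  biomarker <- match.arg(biomarker)
  m <- measurements[measurements$biomarker == biomarker, , drop = FALSE]
  pre <- unique(m$patient_id[m$day >= -30 & m$day <= -1])
  at0 <- unique(m$patient_id[m$day %in% c(0L, 1L)])
  sort(intersect(pre, at0))
}

#' @param measurements as in [select_cohort()].
#' @return patient ids eligible for both CRP and PA.
#' @rdname select_cohort
#' @export
eligible_both <- function(measurements) {
  intersect(select_cohort(measurements, "CRP"), select_cohort(measurements, "PA"))
}

#' Daily mean series
#'
#' Pools all specimens of one biomarker across the given patients and
#' returns, for every relative day with at least one specimen, the
#' per-day summary (mean by default, optionally median) and the specimen
#' count. Multiple same-day specimens from one patient all contribute:
#' the series summarises specimens, not patients.
#'
#' @param measurements measurement data frame.
#' @param biomarker `"CRP"` or `"PA"`.
#' @param patient_ids optional: restrict to these patients (e.g. the
#'   eligible cohort from [select_cohort()]).
#' @param fun `"mean"` (default) or `"median"`.
#' @return data frame with columns `day`, `value`, `n`, ordered by day;
#'   days without specimens are absent. Attribute `biomarker` records the
#'   series' biomarker.
#' @export
daily_means <- function(measurements, biomarker = c("CRP", "PA"),
                        patient_ids = NULL, fun = c("mean", "median")) {
  biomarker <- match.arg(biomarker)
  fun <- match.arg(fun)
  m <- measurements[measurements$biomarker == biomarker, , drop = FALSE]
  if (!is.null(patient_ids))
    m <- m[m$patient_id %in% patient_ids, , drop = FALSE]
  if (nrow(m) == 0L)
    return(structure(data.frame(day = integer(), value = numeric(), n = integer()),
                     biomarker = biomarker))
  f <- factor(m$day, levels = sort(unique(m$day)))
  value <- as.numeric(tapply(m$value, f, if (fun == "mean") mean else stats::median))
  out <- data.frame(day = as.integer(levels(f)),
                    value = value,
                    n = as.integer(table(f)))
  attr(out, "biomarker") <- biomarker
  out
}

#' Cohort flow report
#'
#' Tabulates how many patients enter the analysis and how many survive each
#' eligibility filter: at least one pre-diagnosis and one diagnosis-day
#' measurement per biomarker, eligibility for both biomarkers, and
#' eligibility for the per-patient two-window slope analysis.
#'
#' @param measurements windowed measurement data frame.
#' @param patients patient table (`patient_id`, `group`); its row count is
#'   the number entering.
#' @return named list of counts: `entering`, `eligible_crp`, `eligible_pa`,
#'   `eligible_both`, `slope_eligible_crp`, `slope_eligible_pa`.
#' @export
cohort_flow_report <- function(measurements, patients) {
  crp <- select_cohort(measurements, "CRP")
  pa <- select_cohort(measurements, "PA")
  sp_crp <- slope_pairs(measurements, biomarker = "CRP")
  sp_pa <- slope_pairs(measurements, biomarker = "PA")
  list(entering = nrow(patients),
       eligible_crp = length(crp),
       eligible_pa = length(pa),
       eligible_both = length(intersect(crp, pa)),
       slope_eligible_crp = nrow(sp_crp),
       slope_eligible_pa = nrow(sp_pa))
}

#' Read a long-format measurement table
#'
#' Accepts either dialect of the pipeline's delimited input: relative-day
#' (`patient_id, biomarker, day, value, below_lod`) or calendar
#' (`patient_id, biomarker, specimen_date, value, below_lod` plus a patient
#' table carrying `index_date`), in which case relative days are computed
#' with [assign_relative_day()].
#'
#' @param path CSV file with a header row.
#' @param patients optional patient table (needed for the calendar dialect;
#'   columns `patient_id`, `index_date`).
#' @return measurement data frame in the relative-day dialect.
#' @export
read_measurements <- function(path, patients = NULL) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("day" %in% names(m)) {
    need <- c("patient_id", "biomarker", "day", "value")
  } else if ("specimen_date" %in% names(m)) {
    if (is.null(patients) || !"index_date" %in% names(patients))
      stop("calendar-dialect input needs a patient table with an index_date column")
    idx <- patients$index_date[match(m$patient_id, patients$patient_id)]
    if (anyNA(idx)) stop("every measurement needs a patient with an index date")
    m$day <- assign_relative_day(m$specimen_date, idx)
    m$specimen_date <- NULL
    need <- c("patient_id", "biomarker", "day", "value")
  } else {
    stop("measurement table must have a 'day' or 'specimen_date' column")
  }
  if (!all(need %in% names(m)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  if (is.null(m$below_lod)) m$below_lod <- FALSE
  m$below_lod <- as.logical(m$below_lod)
  if (any(!is.finite(m$value)) || any(m$value < 0))
    stop("measurement values must be finite and non-negative")
  m
}
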