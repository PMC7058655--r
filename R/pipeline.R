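#' Configure an end-to-end analysis run
#'
#' @param scenario a [bsi_scenario()] object or path to a scenario YAML
#'   file (simulate mode), or `NULL` when reading measurement files.
#' @param measurements_path,patients_path input CSVs (ignored in simulate
#'   mode). Either dialect accepted by [read_measurements()].
#' @param out_dir output directory; created if absent.
#' @param biomarkers biomarkers to analyse.
#' @param window analysis window in relative days.
#' @param lod CRP limit of detection (mg/l).
#' @param pa_floor PA implausibility floor (g/l).
#' @param c_search,grid_step change-point search settings.
#' @param n_reps bootstrap replicates for CIs and group comparisons.
#' @param compare_groups run pairwise group comparisons (default `TRUE`).
#' @param figures write figures (default `TRUE`).
#' @param seed root seed; per-stage substreams are derived from it.
#' @return a validated `"bsi_run_config"` list.
#' @export
run_config <- function(scenario = NULL, measurements_path = NULL,
                       patients_path = NULL, out_dir,
                       biomarkers = c("CRP", "PA"), window = c(-30, 1),
                       lod = 10, pa_floor = 11,
                       c_search = c(-29, 0), grid_step = 0.1,
                       n_reps = 1000, compare_groups = TRUE,
                       figures = TRUE, seed = 1) {
  cfg <- structure(list(scenario = scenario,
                        measurements_path = measurements_path,
                        patients_path = patients_path,
                        out_dir = out_dir, biomarkers = biomarkers,
                        window = window, lod = lod, pa_floor = pa_floor,
                        c_search = c_search, grid_step = grid_step,
                        n_reps = n_reps, compare_groups = compare_groups,
                        figures = figures, seed = seed),
                   class = "bsi_run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  fail <- function(msg) stop("invalid run config: ", msg, call. = FALSE)
  if (is.null(cfg$scenario) &&
      (is.null(cfg$measurements_path) || is.null(cfg$patients_path)))
    fail("either a scenario or measurement + patient paths are required")
  if (length(cfg$window) != 2L || cfg$window[1] >= cfg$window[2])
    fail("window start must be before window end")
  if (!is.numeric(cfg$grid_step) || cfg$grid_step <= 0)
    fail("grid_step must be > 0")
  if (cfg$n_reps < 1) fail("n_reps must be >= 1")
  if (!all(cfg$biomarkers %in% c("CRP", "PA"))) fail("unknown biomarker")
  if (cfg$lod <= 0) fail("lod must be > 0")
  invisible(cfg)
}

#' Run the full kinetics analysis
#'
#' Orchestrates the pipeline end to end: acquire a cohort (simulate from a
#' scenario, or read measurement/patient tables), window and clean it
#' (LOD imputation for CRP, implausible-value exclusion for PA), filter to
#' the eligible cohort, fit the broken stick to each biomarker's daily
#' means with patient-bootstrap CIs (overall and per microbial group),
#' compare parameters between groups, compute per-patient two-window
#' slopes, and write every stage's output plus figures and a manifest to
#' the output directory. One root seed spawns independent per-stage
#' substreams, so a rerun with the same config is identical.
#'
#' Outputs written under `out_dir`: `measurements.csv`, `patients.csv`
#' (cleaned cohort), `eligibility.json`, `daily_means_<biomarker>.csv`,
#' `fits.json`, `comparisons.csv` (when groups are compared),
#' `slope_pairs_<biomarker>.csv`, `slope_summary.json`, figures
#' (`fig_counts.pdf`, `fig_fit_<biomarker>.pdf`,
#' `fig_slopes_<biomarker>.pdf`) and `manifest.json`. Figures are drawn
#' from the files just written, never from in-memory state.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with the fitted objects, tables and the
#'   manifest (`class "bsi_run"`).
#' @export
run_analysis <- function(config) {
  validate_run_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(cfg$seed))
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4L)  # sim, impute, ci, compare

  # --- acquire ---------------------------------------------------------
  if (!is.null(cfg$scenario)) {
    sc <- if (is.character(cfg$scenario)) read_scenario(cfg$scenario) else cfg$scenario
    cohort <- simulate_cohort(sc, seed = stage_seed[1])
    meas <- cohort$measurements
    patients <- cohort$patients
  } else {
    patients <- utils::read.csv(cfg$patients_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "group") %in% names(patients)))
      stop("patient table must have columns patient_id and group")
    meas <- read_measurements(cfg$measurements_path, patients)
  }

  # --- preprocess ------------------------------------------------------
  meas <- window_measurements(meas, cfg$window)
  is_crp <- meas$biomarker == "CRP"
  set.seed(stage_seed[2])
  crp <- impute_below_lod(meas[is_crp, , drop = FALSE], lod = cfg$lod)
  pa <- exclude_implausible_pa(meas[!is_crp, , drop = FALSE], floor = cfg$pa_floor)
  n_pa_excluded <- attr(pa, "n_excluded")
  meas <- rbind(crp, pa)

  utils::write.csv(meas, file.path(cfg$out_dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(patients, file.path(cfg$out_dir, "patients.csv"), row.names = FALSE)

  flow <- cohort_flow_report(meas, patients)
  flow$pa_values_excluded <- n_pa_excluded
  jsonlite::write_json(flow, file.path(cfg$out_dir, "eligibility.json"),
                       auto_unbox = TRUE, digits = NA)
  for (b in cfg$biomarkers)
    if (flow[[paste0("eligible_", tolower(b))]] == 0L)
      stop("empty eligible cohort for ", b)

  # --- fits ------------------------------------------------------------
  fits <- list(); fit_records <- list()
  groups_present <- sort(unique(patients$group))
  for (b in cfg$biomarkers) {
    elig <- select_cohort(meas, b)
    dm <- daily_means(meas, b, patient_ids = elig)
    utils::write.csv(dm, file.path(cfg$out_dir, paste0("daily_means_", b, ".csv")),
                     row.names = FALSE)
    bb <- bsr_boot(meas, b, patient_ids = elig, n_reps = cfg$n_reps,
                   seed = stage_seed[3], c_search = cfg$c_search,
                   grid_step = cfg$grid_step)
    fits[[b]] <- list(all = bb)
    fit_records[[b]] <- list(all = fit_record(bb))
    for (g in groups_present) {
      gb <- tryCatch(
        bsr_boot(meas, b, patient_ids = group_ids(meas, patients, b, g),
                 n_reps = cfg$n_reps, seed = stage_seed[3],
                 c_search = cfg$c_search, grid_step = cfg$grid_step),
        error = function(e) conditionMessage(e))
      if (is.character(gb)) {
        fit_records[[b]][[g]] <- list(error = gb)
      } else {
        fits[[b]][[g]] <- gb
        fit_records[[b]][[g]] <- fit_record(gb)
      }
    }
  }
  jsonlite::write_json(fit_records, file.path(cfg$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- group comparisons ----------------------------------------------
  comparisons <- NULL
  if (cfg$compare_groups && length(groups_present) >= 2L) {
    rows <- list()
    pairs <- utils::combn(groups_present, 2L, simplify = FALSE)
    for (b in cfg$biomarkers) for (pr in pairs) for (p in c("c", "slope_pre", "slope_post")) {
      d <- tryCatch(
        bsr_group_diff(meas, patients, b, pr[1], pr[2], parameter = p,
                       n_reps = cfg$n_reps, seed = stage_seed[4],
                       c_search = cfg$c_search, grid_step = cfg$grid_step),
        error = function(e) conditionMessage(e))
      rows[[length(rows) + 1L]] <- if (is.character(d))
        data.frame(biomarker = b, parameter = p, group_a = pr[1], group_b = pr[2],
                   estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                   significant = NA, n_failed = NA_integer_, note = d)
      else
        data.frame(biomarker = b, parameter = p, group_a = pr[1], group_b = pr[2],
                   estimate = d$estimate, lower = d$ci95[1], upper = d$ci95[2],
                   significant = d$significant, n_failed = d$n_failed, note = "")
    }
    comparisons <- do.call(rbind, rows)
    utils::write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }

  # --- individual slopes ----------------------------------------------
  slopes <- list(); slope_summaries <- list()
  for (b in cfg$biomarkers) {
    sp <- slope_pairs(meas, patients, b)
    utils::write.csv(sp, file.path(cfg$out_dir, paste0("slope_pairs_", b, ".csv")),
                     row.names = FALSE)
    slopes[[b]] <- sp
    if (nrow(sp) > 0) {
      sm <- summarize_slope_patterns(sp, b)
      sm$quartiles <- lapply(sm$quartiles, function(m)
        as.data.frame(cbind(group = rownames(m), as.data.frame(m))))
      slope_summaries[[b]] <- sm
    }
  }
  jsonlite::write_json(slope_summaries, file.path(cfg$out_dir, "slope_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- figures (from the saved files, not in-memory state) -------------
  if (cfg$figures) run_figures(cfg$out_dir, cfg$biomarkers)

  # --- manifest --------------------------------------------------------
  cfg_json <- file.path(cfg$out_dir, "config.json")
  cfg_list <- cfg
  cfg_list$scenario <- if (is.null(cfg$scenario)) NULL
    else if (is.character(cfg$scenario)) cfg$scenario else "inline bsi_scenario"
  jsonlite::write_json(unclass(cfg_list), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(package = "bsikinetics",
                   version = as.character(utils::packageVersion("bsikinetics")),
                   r_version = as.character(getRversion()),
                   seed = cfg$seed, stage_seeds = stage_seed,
                   config_md5 = unname(tools::md5sum(cfg_json)),
                   files = sort(list.files(cfg$out_dir)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  out <- list(config = cfg, flow = flow, fits = fits, comparisons = comparisons,
              slopes = slopes, slope_summaries = slope_summaries,
              manifest = manifest, out_dir = cfg$out_dir)
  class(out) <- "bsi_run"
  invisible(out)
}

# machine-readable record of one bootstrapped fit
fit_record <- function(bb) {
  cf <- coef(bb$fit)
  list(parameters = as.list(cf),
       ci = list(c = unname(bb$ci["c", ]),
                 level_at_c = unname(bb$ci["level_at_c", ]),
                 slope_pre = unname(bb$ci["slope_pre", ]),
                 slope_post = unname(bb$ci["slope_post", ])),
       sse = bb$fit$sse, n_days = bb$fit$n, n_patients = bb$n_patients,
       n_reps = bb$n_reps, n_failed = bb$n_failed, seed = bb$seed,
       c_search = bb$fit$c_search, grid_step = bb$fit$grid_step)
}

# figures rebuilt from the stage files on disk
run_figures <- function(out_dir, biomarkers) {
  meas <- utils::read.csv(file.path(out_dir, "measurements.csv"),
                          stringsAsFactors = FALSE)
  fits <- jsonlite::read_json(file.path(out_dir, "fits.json"))

  grDevices::pdf(file.path(out_dir, "fig_counts.pdf"), width = 7, height = 4)
  graphics::par(mfrow = c(1, length(biomarkers)))
  for (b in biomarkers) {
    tab <- table(factor(meas$day[meas$biomarker == b], levels = -30:1))
    graphics::barplot(tab, main = paste(b, "specimens per day"),
                      xlab = "day relative to diagnosis", ylab = "specimens")
  }
  grDevices::dev.off()

  for (b in biomarkers) {
    dm <- utils::read.csv(file.path(out_dir, paste0("daily_means_", b, ".csv")))
    fr <- fits[[b]]$all$parameters
    grDevices::pdf(file.path(out_dir, paste0("fig_fit_", b, ".pdf")),
                   width = 6, height = 4)
    graphics::plot(dm$day, dm$value, xlab = "day relative to diagnosis",
                   ylab = paste(b, "daily mean"), main = paste(b, "course"))
    stick <- function(t) fr$level_at_c + fr$slope_pre * pmin(t - fr$c, 0) +
      fr$slope_post * pmax(t - fr$c, 0)
    tt <- sort(c(seq(min(dm$day), max(dm$day), length.out = 300), fr$c))
    graphics::lines(tt, stick(tt), col = "red3", lwd = 2)
    usr <- graphics::par("usr")
    graphics::arrows(fr$c, stick(fr$c) + 0.25 * (usr[4] - usr[3]),
                     fr$c, stick(fr$c) + 0.05 * (usr[4] - usr[3]),
                     length = 0.1, col = "blue3")
    grDevices::dev.off()

    sp <- utils::read.csv(file.path(out_dir, paste0("slope_pairs_", b, ".csv")),
                          stringsAsFactors = FALSE)
    if (nrow(sp)) {
      class(sp) <- c("slope_pairs", "data.frame")
      grDevices::pdf(file.path(out_dir, paste0("fig_slopes_", b, ".pdf")),
                     width = 5, height = 5)
      plot(sp, main = paste(b, "individual slopes"))
      grDevices::dev.off()
    }
  }
  invisible(NULL)
}

#' @export
print.bsi_run <- function(x, ...) {
  cat("CA-BSI biomarker kinetics run ->", x$out_dir, "\n")
  cat("  patients entering:", x$flow$entering,
      " eligible CRP:", x$flow$eligible_crp,
      " PA:", x$flow$eligible_pa,
      " both:", x$flow$eligible_both, "\n")
  for (b in names(x$fits)) {
    cf <- coef(x$fits[[b]]$all$fit)
    cat(sprintf("  %s: change at day %.1f, slopes %.2f / %.2f per day\n",
                b, cf["c"], cf["slope_pre"], cf["slope_post"]))
  }
  invisible(x)
}
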