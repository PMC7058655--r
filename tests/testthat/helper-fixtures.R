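# shared fixtures: all synthetic, built in code at test time

# piecewise-linear mean with change-point cc
stick <- function(day, cc, level, pre, post) {
  level + pre * pmin(day - cc, 0) + post * pmax(day - cc, 0)
}

# a scenario with no noise and exhaustive daily sampling; identical kinetics
# for all groups unless overridden
zero_noise_scenario <- function(n = 20,
                                crp = bsi_kinetics(-3, 100, -2, 35),
                                pa = bsi_kinetics(-1.3, 30, 0.1, -1.8),
                                kinetics = NULL, crp_noise_sd_log = 0,
                                pa_noise_sd = 0, ...) {
  profile <- rep(1, 32)
  names(profile) <- as.character(-30:1)
  if (is.null(kinetics)) {
    kin <- list(CRP = crp, PA = pa)
    kinetics <- list(gram_pos = kin, gram_neg = kin, polymicrobial = kin)
  }
  bsi_scenario(n_patients = n, kinetics = kinetics,
               sampling_profile = profile,
               crp_noise_sd_log = crp_noise_sd_log,
               pa_noise_sd = pa_noise_sd, ...)
}

# hand-built measurement table; below_lod defaults to FALSE
meas_df <- function(patient_id, biomarker, day, value, below_lod = FALSE) {
  n <- length(day)
  data.frame(patient_id = rep_len(patient_id, n),
             biomarker = rep_len(biomarker, n),
             day = day, value = rep_len(value, n),
             below_lod = rep_len(below_lod, n), stringsAsFactors = FALSE)
}

# independent exhaustive broken-stick search: per-candidate lm() refit,
# admissibility re-derived from scratch (the oracle for the profiled fit)
oracle_bsr <- function(day, value, c_from = -29, c_to = 0, step = 0.1) {
  grid <- seq(c_from, c_to, by = step)
  ud <- sort(unique(day))
  ok <- vapply(grid, function(cc) sum(ud <= cc) >= 2 && sum(ud > cc) >= 2,
               logical(1))
  grid <- grid[ok]
  sse <- vapply(grid, function(cc) {
    f <- lm(value ~ I(pmin(day - cc, 0)) + I(pmax(day - cc, 0)))
    sum(resid(f)^2)
  }, numeric(1))
  best <- which(sse <= min(sse) + 1e-9 * max(1, abs(min(sse))))
  i <- best[which.min(abs(grid[best]))]
  cc <- grid[i]
  f <- lm(value ~ I(pmin(day - cc, 0)) + I(pmax(day - cc, 0)))
  list(c = cc, sse = sse[i], level_at_c = unname(coef(f)[1]),
       slope_pre = unname(coef(f)[2]), slope_post = unname(coef(f)[3]))
}

# paper-reported 95% CIs used as recovery bands in the acceptance suite
paper_ci <- list(
  crp_c = c(-3.6, -2.6), crp_slope_pre = c(-2.0, -0.9),
  crp_slope_post = c(31.3, 41.4),
  pa_c = c(-2.4, -0.8), pa_slope_pre = c(0.03, 0.10),
  pa_slope_post = c(-2.4, -1.3))
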