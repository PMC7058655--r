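test_that("scenario invariants are enforced with named failures", {
  expect_error(zero_noise_scenario(group_probs = c(gram_pos = 0.5, gram_neg = 0.5,
                                                   polymicrobial = 0.1)),
               "sum to 1")
  expect_error(zero_noise_scenario(crp_lod = 0), "crp_lod")
  expect_error(zero_noise_scenario(pa_noise_sd = -1), "pa_noise_sd")
  bad <- zero_noise_scenario()
  bad$sampling_profile[["-10"]] <- 1
  bad$sampling_profile[["0"]] <- 0.5
  expect_error(validate_scenario(bad), "day 0")
  bad2 <- zero_noise_scenario()
  bad2$sampling_profile[["-5"]] <- 1.4
  expect_error(validate_scenario(bad2), "\\[0, 1\\]")
  expect_error(bsi_kinetics(c = 1.5, 50, 0, 1), "strictly inside")
  expect_error(bsi_kinetics(c = -30, 50, 0, 1), "strictly inside")
})

test_that("the reference scenario carries the reported kinetics", {
  sc <- default_paper_scenario()
  expect_equal(sum(sc$group_probs), 1)
  for (g in c("gram_pos", "gram_neg", "polymicrobial")) {
    expect_equal(sc$kinetics[[g]]$CRP$c, -3.1)
    expect_equal(sc$kinetics[[g]]$CRP$slope_pre, -1.5)
    expect_equal(sc$kinetics[[g]]$CRP$slope_post, 36.3)
    expect_equal(sc$kinetics[[g]]$PA$c, -1.3)
    expect_equal(sc$kinetics[[g]]$PA$slope_post, -1.8)
  }
  # sampling rises sharply into the diagnosis day
  sp <- sc$sampling_profile
  expect_true(sp[["0"]] > sp[["-2"]] && sp[["-2"]] > sp[["-10"]])
  expect_equal(unname(sp[["-10"]]), unname(sp[["-25"]]))  # flat far from D0
})

test_that("generation is a pure function of scenario and seed", {
  sc <- default_paper_scenario(40)
  a <- simulate_cohort(sc, seed = 42)
  b <- simulate_cohort(sc, seed = 42)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$patients, b$patients)
  d <- simulate_cohort(sc, seed = 43)
  expect_false(identical(a$measurements, d$measurements))
})

test_that("zero-noise cohorts lie exactly on the generating stick", {
  sc <- zero_noise_scenario(10)
  coh <- simulate_cohort(sc, seed = 1)
  m <- coh$measurements
  expect_equal(nrow(m), 10 * 32 * 2)  # exhaustive sampling, both biomarkers
  for (b in c("CRP", "PA")) {
    mb <- m[m$biomarker == b, ]
    k <- sc$kinetics$gram_pos[[b]]
    expect_equal(mb$value, kinetics_mean(k, mb$day))
  }
})

test_that("per-day specimen counts follow the sampling profile", {
  sc <- default_paper_scenario(120)
  counts <- matrix(0, 40, 32)
  for (s in 1:40) {
    m <- simulate_cohort(sc, seed = 100 + s)$measurements
    counts[s, ] <- table(factor(m$day[m$biomarker == "CRP"], levels = -30:1))
  }
  p_hat <- colSums(counts) / (40 * 120)
  p <- unname(sc$sampling_profile[as.character(-30:1)])
  se <- sqrt(p * (1 - p) / (40 * 120))
  expect_true(all(abs(p_hat - p) <= 3 * se + 1e-12))
})

test_that("no CRP value is below the detection limit without a flag", {
  # low level + heavy noise drives many values under the limit
  kin <- list(CRP = bsi_kinetics(-3, 15, 0, 10),
              PA = bsi_kinetics(-1.3, 30, 0, -2))
  sc <- zero_noise_scenario(50, kinetics = list(gram_pos = kin, gram_neg = kin,
                                                polymicrobial = kin))
  sc$crp_noise_sd_log <- 0.8
  coh <- simulate_cohort(sc, seed = 9)
  crp <- coh$measurements[coh$measurements$biomarker == "CRP", ]
  expect_gt(sum(crp$below_lod), 0)
  expect_true(all(crp$value >= 10 | crp$below_lod))
  expect_true(all(crp$value[crp$below_lod] == 10))  # coded as the LOD
})

test_that("implausibly low PA values are emitted for the exclusion filter", {
  kin <- list(CRP = bsi_kinetics(-3, 100, 0, 10),
              PA = bsi_kinetics(-1.3, 14, 0, -2))
  sc <- zero_noise_scenario(50, kinetics = list(gram_pos = kin, gram_neg = kin,
                                                polymicrobial = kin))
  sc$pa_noise_sd <- 4
  coh <- simulate_cohort(sc, seed = 10)
  pa <- coh$measurements[coh$measurements$biomarker == "PA", ]
  expect_gt(sum(pa$value < 11), 0)   # emitted, not silently removed
  expect_true(all(pa$value >= 0))    # but truncated at zero
})

test_that("scenarios round-trip through YAML", {
  sc <- default_paper_scenario(77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$n_patients, 77)
  expect_equal(back$kinetics$gram_neg$CRP$slope_post, 36.3)
  expect_identical(simulate_cohort(back, 5)$measurements,
                   simulate_cohort(sc, 5)$measurements)
})

test_that("cohorts round-trip through delimited text", {
  coh <- simulate_cohort(default_paper_scenario(15), seed = 2)
  mp <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, mp, pp)
  back <- read_cohort(mp, pp)
  expect_equal(back$measurements$value, coh$measurements$value)
  expect_identical(back$measurements$below_lod, coh$measurements$below_lod)
  expect_identical(back$patients$group, coh$patients$group)
})
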