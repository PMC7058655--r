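test_that("relative days are whole-day differences from the culture date", {
  expect_identical(assign_relative_day("2004-03-10", "2004-03-10"), 0L)
  expect_identical(assign_relative_day("2004-03-07", "2004-03-10"), -3L)
  expect_identical(assign_relative_day("2004-03-11", "2004-03-10"), 1L)
  expect_identical(assign_relative_day(c("2004-02-09", "2004-03-12"),
                                       "2004-03-10"), c(-30L, 2L))
  expect_error(assign_relative_day(NA, "2004-03-10"), "valid")
})

test_that("detection-limit imputation draws uniformly on 0..9 and touches nothing else", {
  m <- meas_df("p1", "CRP", rep(-5, 6), c(10, 57, 10, 120, 10, 8.5),
               below_lod = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  set.seed(4)
  out <- impute_below_lod(m)
  expect_true(all(out$value[m$below_lod] %in% 0:9))
  expect_identical(out$value[!m$below_lod], c(57, 120))
  expect_identical(out$below_lod, m$below_lod)  # provenance retained

  # empirical mean of many draws matches the discrete-uniform law
  big <- meas_df("p", "CRP", rep(0, 10000), rep(10, 10000), below_lod = TRUE)
  set.seed(1)
  v <- impute_below_lod(big)$value
  se <- sqrt(sum((0:9 - 4.5)^2) / 10) / sqrt(10000)
  expect_lt(abs(mean(v) - 4.5), 3 * se)
  expect_setequal(unique(v), 0:9)

  set.seed(2)
  vc <- impute_below_lod(big, method = "continuous")$value
  expect_true(all(vc >= 0 & vc < 10))
  expect_false(all(vc == round(vc)))

  expect_error(impute_below_lod(meas_df("p", "PA", 0, 30)), "PA")
})

test_that("implausible PA values are excluded at a strict 11 g/l boundary", {
  m <- meas_df("p", "PA", c(-3, -2, -1), c(10.9, 11.0, 28))
  out <- exclude_implausible_pa(m)
  expect_identical(out$value, c(11.0, 28))
  expect_identical(attr(out, "n_excluded"), 1L)
  empty <- exclude_implausible_pa(meas_df(character(), character(),
                                          integer(), numeric()))
  expect_identical(nrow(empty), 0L)
  set.seed(8)
  v <- runif(100, 5, 40)
  out2 <- exclude_implausible_pa(meas_df("p", "PA", seq_along(v) %% 30 - 29, v))
  expect_identical(out2$value, v[v >= 11])
  expect_identical(attr(out2, "n_excluded"), sum(v < 11))
})

test_that("eligibility requires a pre-diagnosis and a diagnosis-day measurement", {
  m <- rbind(meas_df("a", "CRP", c(-5, 0), c(50, 100)),
             meas_df("b", "CRP", -5, 40),
             meas_df("c", "CRP", c(0, 1), c(90, 95)),
             meas_df("d", "CRP", c(-30, 1), c(20, 200)),
             meas_df("e", "PA", c(-2, 0), c(30, 25)))
  expect_identical(select_cohort(m, "CRP"), c("a", "d"))
  expect_identical(select_cohort(m, "PA"), "e")
  expect_identical(eligible_both(m), character(0))
})

test_that("eligibility matches a brute-force evaluation and is order-independent", {
  set.seed(21)
  m <- meas_df(sample(sprintf("p%02d", 1:50), 400, replace = TRUE),
               sample(c("CRP", "PA"), 400, replace = TRUE),
               sample(-30:1, 400, replace = TRUE),
               runif(400, 5, 200))
  for (b in c("CRP", "PA")) {
    brute <- sort(Filter(function(p) {
      d <- m$day[m$patient_id == p & m$biomarker == b]
      any(d >= -30 & d <= -1) && any(d %in% c(0, 1))
    }, unique(m$patient_id)))
    expect_identical(select_cohort(m, b), brute)
    shuffled <- m[sample(nrow(m)), ]
    expect_identical(select_cohort(shuffled, b), brute)
    # idempotent: filtering the already-eligible cohort changes nothing
    m2 <- m[m$patient_id %in% brute, ]
    expect_identical(select_cohort(m2, b), brute)
  }
})

test_that("daily means pool specimens, not patients", {
  m <- rbind(meas_df("a", "CRP", c(-7, -7), c(5, 15)),   # same-day duplicates
             meas_df("b", "CRP", -7, 10),
             meas_df("b", "CRP", -3, 40))
  dm <- daily_means(m, "CRP")
  expect_equal(dm$value[dm$day == -7], mean(c(5, 15, 10)))
  expect_equal(dm$n[dm$day == -7], 3L)
  expect_equal(dm$n[dm$day == -3], 1L)
  # conservation: counts sum to the measurements in the series
  expect_identical(sum(dm$n), nrow(m))
  # days without specimens are absent, series is day-ordered
  expect_identical(dm$day, c(-7L, -3L))
})

test_that("daily means of a zero-noise cohort equal the generating stick", {
  sc <- zero_noise_scenario(8)
  coh <- simulate_cohort(sc, seed = 3)
  dm <- daily_means(coh$measurements, "PA",
                    patient_ids = select_cohort(coh$measurements, "PA"))
  expect_equal(dm$value, kinetics_mean(sc$kinetics$gram_pos$PA, dm$day))
  expect_identical(dm$n, rep(8L, 32))
  # median option agrees in the degenerate case
  dmm <- daily_means(coh$measurements, "PA", fun = "median")
  expect_equal(dmm$value, dm$value)
})

test_that("both input dialects read to the same relative-day table", {
  pats <- data.frame(patient_id = c("a", "b"), group = "gram_pos",
                     index_date = c("2004-03-10", "2004-06-01"))
  cal <- data.frame(patient_id = c("a", "a", "b"), biomarker = "CRP",
                    specimen_date = c("2004-03-07", "2004-03-10", "2004-05-31"),
                    value = c(50, 100, 70), below_lod = FALSE)
  rel <- data.frame(patient_id = c("a", "a", "b"), biomarker = "CRP",
                    day = c(-3L, 0L, -1L), value = c(50, 100, 70),
                    below_lod = FALSE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cal, f1, row.names = FALSE)
  write.csv(rel, f2, row.names = FALSE)
  m1 <- read_measurements(f1, pats)
  m2 <- read_measurements(f2)
  expect_identical(m1[c("patient_id", "day", "value")],
                   m2[c("patient_id", "day", "value")])
  expect_error(read_measurements(f1), "index_date")
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_measurements(bad), "column")
})
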