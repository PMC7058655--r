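test_that("noiseless piecewise-linear series are recovered exactly", {
  cases <- list(c(-3, 100, -2, 35), c(-5.5, 80, 0, 40), c(-10, 30, 0.5, -2))
  for (p in cases) {
    d <- data.frame(day = -30:1)
    d$value <- stick(d$day, p[1], p[2], p[3], p[4])
    fit <- bsr(value ~ day, d, c_search = c(-29, 0))
    expect_equal(unname(coef(fit)), p, tolerance = 1e-8)
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("prediction anchors at the change-point and is piecewise linear", {
  d <- data.frame(day = -30:1)
  d$value <- stick(d$day, -3, 80, 0, 40)
  fit <- bsr(value ~ day, d)
  cc <- coef(fit)[["c"]]
  expect_equal(predict(fit, cc), 80, tolerance = 1e-8)
  expect_equal(predict(fit, -1), 160, tolerance = 1e-8)  # 80 + 40 * 2
  # continuity at the change-point
  eps <- 1e-9
  expect_equal(predict(fit, cc - eps), predict(fit, cc + eps), tolerance = 1e-6)
  # newdata as a data frame uses the formula's day variable
  expect_equal(predict(fit, data.frame(day = c(-10, 0))),
               stick(c(-10, 0), -3, 80, 0, 40), tolerance = 1e-8)
  expect_warning(predict(fit, 5), "extrapolat")
})

test_that("equal slopes degenerate to a single straight line", {
  d <- data.frame(day = -30:1)
  d$value <- stick(d$day, -7, 50, 3, 3)  # one line of slope 3
  fit <- bsr(value ~ day, d)
  expect_equal(predict(fit, d$day), 50 + 3 * (d$day + 7), tolerance = 1e-6)
  expect_equal(fit$sse, fit$sse_line, tolerance = 1e-8)
})

test_that("profiled minimiser matches an independent exhaustive search", {
  set.seed(11)
  for (i in 1:10) {
    d <- data.frame(day = -30:1)
    d$value <- stick(d$day, runif(1, -15, -1), 50, runif(1, -3, 1),
                     runif(1, 5, 40)) + rnorm(32, sd = 5)
    fit <- bsr(value ~ day, d, c_search = c(-29, 0), grid_step = 0.1)
    orc <- oracle_bsr(d$day, d$value)
    expect_identical(coef(fit)[["c"]], orc$c)
    expect_equal(fit$sse, orc$sse, tolerance = 1e-8)
    expect_equal(coef(fit)[["slope_pre"]], orc$slope_pre, tolerance = 1e-8)
    expect_equal(coef(fit)[["slope_post"]], orc$slope_post, tolerance = 1e-8)
  }
})

test_that("broken-stick SSE never exceeds the single-line SSE", {
  set.seed(7)
  for (i in 1:20) {
    d <- data.frame(day = -30:1, value = rnorm(32, 50, 10))
    fit <- bsr(value ~ day, d)
    expect_lte(fit$sse, fit$sse_line + 1e-9)
  }
})

test_that("fits are equivariant under value and day shifts", {
  set.seed(3)
  d <- data.frame(day = -30:1)
  d$value <- stick(d$day, -4, 60, -1, 20) + rnorm(32, sd = 3)
  f0 <- bsr(value ~ day, d, c_search = c(-29, 0))
  up <- transform(d, value = value + 100)
  f1 <- bsr(value ~ day, up, c_search = c(-29, 0))
  expect_equal(coef(f1)[["level_at_c"]], coef(f0)[["level_at_c"]] + 100,
               tolerance = 1e-8)
  expect_equal(coef(f1)[c("c", "slope_pre", "slope_post")],
               coef(f0)[c("c", "slope_pre", "slope_post")], tolerance = 1e-8)
  sh <- transform(d, day = day + 5)
  f2 <- bsr(value ~ day, sh, c_search = c(-24, 5))
  expect_equal(coef(f2)[["c"]], coef(f0)[["c"]] + 5, tolerance = 1e-8)
  expect_equal(coef(f2)[c("slope_pre", "slope_post")],
               coef(f0)[c("slope_pre", "slope_post")], tolerance = 1e-8)
})

test_that("SSE ties break toward the latest admissible change-point", {
  d <- data.frame(day = -30:1, value = rep(10, 32))  # flat: every c ties at 0
  fit <- bsr(value ~ day, d, c_search = c(-29, 0), grid_step = 0.1)
  # day 1 is the only day beyond c = 0, so -0.1 is the latest admissible
  expect_equal(coef(fit)[["c"]], -0.1)
})

test_that("change-point error shrinks as noise vanishes", {
  c_true <- -4
  err <- sapply(c(8, 1, 0), function(sd) {
    set.seed(42)
    mean(replicate(30, {
      d <- data.frame(day = -30:1)
      d$value <- stick(d$day, c_true, 80, -1, 30) + rnorm(32, sd = sd)
      abs(coef(bsr(value ~ day, d))[["c"]] - c_true)
    }))
  })
  expect_true(all(diff(err) <= 1e-12))
  expect_equal(err[3], 0, tolerance = 1e-8)
})

test_that("degenerate inputs fail with informative errors", {
  expect_error(bsr(value ~ day, data.frame(day = c(-3, -2, 0), value = 1:3)),
               "4 distinct days")
  d <- data.frame(day = -30:1, value = rnorm(32))
  expect_error(bsr(value ~ day, d, grid_step = 0), "grid_step")
  expect_error(bsr(value ~ day, d, c_search = c(0, -29)), "c_search")
  expect_error(bsr(value ~ day, d, c_search = c(-40, 0)), "day range")
})

test_that("optional refinement interpolates off-grid change-points", {
  d <- data.frame(day = -30:1)
  d$value <- stick(d$day, -3.37, 90, -1, 25)
  fit <- bsr(value ~ day, d, c_search = c(-29, 0), refine = TRUE)
  expect_equal(coef(fit)[["c"]], -3.37, tolerance = 1e-4)
})

test_that("specimen-count weights shift the fit toward heavy days", {
  set.seed(5)
  d <- data.frame(day = -30:1)
  d$value <- stick(d$day, -3, 80, -1, 30) + rnorm(32, sd = 6)
  w <- c(rep(1, 28), 5, 10, 40, 25)
  fw <- bsr(value ~ day, d, weights = w)
  # weighted SSE of the weighted fit beats that of the unweighted fit
  f0 <- bsr(value ~ day, d)
  wsse <- function(f) sum(w * (d$value - predict(f, d$day))^2)
  expect_lte(wsse(fw), wsse(f0) + 1e-9)
})
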