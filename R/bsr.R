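#' Broken-stick regression with an estimated change-point
#'
#' Fits a continuous two-segment linear model to a series of (day, value)
#' points. The mean is
#' \deqn{E[y \mid t] = \alpha + \beta_1 \min(t - c, 0) + \beta_2 \max(t - c, 0)}
#' so the two segments meet at the change-point \eqn{c} with level
#' \eqn{\alpha}; continuity at \eqn{c} is structural, not penalised.
#' The change-point is profiled: for every candidate \eqn{c} on a grid the
#' remaining three parameters are solved by (weighted) linear least squares,
#' and the candidate with the smallest residual sum of squares wins. Ties in
#' the profile are broken toward the candidate closest to day 0, i.e. the
#' latest change.
#'
#' @param formula model formula of the form `value ~ day`.
#' @param data a data frame containing the variables in `formula`, typically
#'   a daily-mean series from [daily_means()].
#' @param weights optional non-negative case weights (e.g. daily specimen
#'   counts). Default: unweighted, one point per day.
#' @param c_search numeric length-2 interval searched for the change-point.
#'   Default: one day inside each end of the observed day range.
#' @param grid_step spacing (days) of the change-point grid. Default 0.1.
#' @param refine if `TRUE`, after the grid search the profile is minimised
#'   continuously between the two grid neighbours of the winner
#'   ([stats::optimize()]). Default `FALSE`: the reported change-point lies
#'   exactly on the grid, which keeps the estimator identical to an
#'   exhaustive search at the same resolution.
#'
#' @return an object of class `"bsr"`: a list with components
#'   `coefficients` (named vector `c`, `level_at_c`, `slope_pre`,
#'   `slope_post`), `sse`, `n` (points fitted), `fitted.values`,
#'   `residuals`, `profile` (data frame of candidate change-points and
#'   their minimised SSE), `sse_line` (SSE of the best single straight
#'   line through the same points), `model`, and `call`.
#'
#' @details At least four distinct days are required, and every candidate
#'   change-point must leave at least two distinct days on each side;
#'   candidates that do not are dropped from the grid. The single straight
#'   line is the equal-slopes boundary of this model, so `sse <= sse_line`
#'   always.
#'
#' @examples
#' # noiseless stick: change at day -3, level 80, slopes -1.5 and 36
#' d <- data.frame(day = -30:1)
#' d$value <- 80 - 1.5 * pmin(d$day + 3, 0) + 36 * pmax(d$day + 3, 0)
#' fit <- bsr(value ~ day, d)
#' coef(fit)
#' @seealso [predict.bsr()], [bsr_boot()], [daily_means()]
#' @export
bsr <- function(formula, data, weights = NULL, c_search = NULL,
                grid_step = 0.1, refine = FALSE) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (ncol(mf) != 2L)
    stop("formula must have exactly one predictor (the day variable)")
  x <- mf[[2L]]
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y)) stop("weights must match the number of points")
  if (any(w < 0)) stop("weights must be non-negative")
  keep <- is.finite(x) & is.finite(y) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]

  if (length(unique(x)) < 4L)
    stop("broken-stick fit needs at least 4 distinct days")
  if (is.null(c_search)) c_search <- c(min(x) + 1, max(x) - 1)
  if (length(c_search) != 2L || c_search[1] >= c_search[2])
    stop("c_search must be an increasing length-2 interval")
  if (c_search[1] < min(x) || c_search[2] > max(x))
    stop("c_search must lie within the observed day range")
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("grid_step must be a single positive number")

  grid <- bsr_c_grid(x, c_search, grid_step)
  if (length(grid) == 0L)
    stop("no admissible change-point candidates: every candidate leaves fewer than 2 distinct days on one side")

  prof <- bsr_profile(x, y, w, grid)
  if (all(!is.finite(prof)))
    stop("all candidate fits were singular")

  best <- bsr_pick(grid, prof)
  c_hat <- best$c

  if (refine) {
    i <- best$index
    lo <- if (i > 1L) grid[i - 1L] else grid[i]
    hi <- if (i < length(grid)) grid[i + 1L] else grid[i]
    if (hi > lo) {
      opt <- stats::optimize(function(cc) bsr_solve(x, y, w, cc)$sse,
                             interval = c(lo, hi), tol = 1e-8)
      if (is.finite(opt$objective) && opt$objective <= prof[i])
        c_hat <- opt$minimum
    }
  }

  sol <- bsr_solve(x, y, w, c_hat)
  # best single straight line on the same points (equal-slopes boundary)
  lf <- stats::lm.wfit(cbind(1, x), y, w)
  sse_line <- sum(w * lf$residuals^2)

  cf <- c(c = c_hat, level_at_c = sol$beta[1],
          slope_pre = sol$beta[2], slope_post = sol$beta[3])
  out <- list(coefficients = cf,
              sse = sol$sse,
              n = length(y),
              fitted.values = sol$fitted,
              residuals = y - sol$fitted,
              profile = data.frame(c = grid, sse = prof),
              sse_line = sse_line,
              c_search = c_search,
              grid_step = grid_step,
              day_range = range(x),
              xname = names(mf)[2L],
              yname = names(mf)[1L],
              model = data.frame(day = x, value = y, weight = w),
              call = match.call())
  class(out) <- "bsr"
  out
}

# admissible candidate grid: >= 2 distinct days strictly on each side
# (points at t <= c belong to the first segment)
bsr_c_grid <- function(x, c_search, grid_step) {
  grid <- seq(c_search[1], c_search[2], by = grid_step)
  ux <- sort(unique(x))
  lower <- vapply(grid, function(cc) sum(ux <= cc) >= 2L, logical(1))
  upper <- vapply(grid, function(cc) sum(ux > cc) >= 2L, logical(1))
  grid[lower & upper]
}

# weighted LS solve of (level, slope_pre, slope_post) at fixed change-point
bsr_solve <- function(x, y, w, cc) {
  X <- cbind(1, pmin(x - cc, 0), pmax(x - cc, 0))
  fit <- stats::lm.wfit(X, y, w)
  if (fit$rank < 3L || anyNA(fit$coefficients))
    return(list(beta = rep(NA_real_, 3), sse = Inf, fitted = rep(NA_real_, length(y))))
  list(beta = unname(fit$coefficients), sse = sum(w * fit$residuals^2),
       fitted = X %*% fit$coefficients)
}

# Profile SSE over the candidate grid, vectorised over candidates.
# The two basis columns pmin(t-c, 0) and pmax(t-c, 0) are orthogonal (their
# pointwise product is identically zero), so the 3x3 normal equations reduce
# to closed form: eliminating the slopes leaves one scalar equation for the
# level, per candidate.
bsr_profile <- function(x, y, w, grid) {
  D <- outer(x, grid, "-")            # days x candidates
  X1 <- pmin(D, 0); X2 <- pmax(D, 0)
  n <- sum(w)
  s1 <- colSums(w * X1); s2 <- colSums(w * X2)
  q1 <- colSums(w * X1^2); q2 <- colSums(w * X2^2)
  b0 <- sum(w * y)
  b1 <- colSums(w * y * X1); b2 <- colSums(w * y * X2)
  den <- n - s1^2 / q1 - s2^2 / q2
  beta0 <- (b0 - s1 * b1 / q1 - s2 * b2 / q2) / den
  beta1 <- (b1 - s1 * beta0) / q1
  beta2 <- (b2 - s2 * beta0) / q2
  sse <- sum(w * y^2) - (beta0 * b0 + beta1 * b1 + beta2 * b2)
  bad <- !is.finite(sse) | q1 <= 0 | q2 <= 0 | den <= 0
  sse[bad] <- Inf
  sse
}

# minimum of the profile; ties (within numerical noise) go to the candidate
# closest to day 0, i.e. the latest change
bsr_pick <- function(grid, prof) {
  m <- min(prof)
  tol <- max(1e-9, 1e-9 * abs(m))
  cand <- which(prof <= m + tol)
  i <- cand[which.min(abs(grid[cand]))]
  list(c = grid[i], index = i, sse = prof[i])
}

#' Predict from a broken-stick fit
#'
#' Evaluates the fitted piecewise-linear mean at new days:
#' `level_at_c + slope_pre * (t - c)` for `t <= c`, and
#' `level_at_c + slope_post * (t - c)` for `t > c`.
#'
#' @param object a `"bsr"` fit.
#' @param newdata a data frame containing the day variable used in the fit,
#'   or a bare numeric vector of days. Missing: the fitted values.
#' @param ... unused.
#' @return numeric vector of predicted concentrations. Days outside the
#'   fitted range are extrapolated with a warning.
#' @export
predict.bsr <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(as.vector(object$fitted.values))
  t <- if (is.numeric(newdata)) newdata else {
    if (!object$xname %in% names(newdata))
      stop("newdata must contain a '", object$xname, "' column")
    newdata[[object$xname]]
  }
  r <- object$day_range
  if (any(t < r[1] | t > r[2], na.rm = TRUE))
    warning("predicting outside the fitted day range [", r[1], ", ", r[2],
            "]: extrapolating the nearest segment")
  cf <- object$coefficients
  unname(cf["level_at_c"] + cf["slope_pre"] * pmin(t - cf["c"], 0) +
           cf["slope_post"] * pmax(t - cf["c"], 0))
}

#' @export
coef.bsr <- function(object, ...) object$coefficients

#' @export
fitted.bsr <- function(object, ...) as.vector(object$fitted.values)

#' @export
residuals.bsr <- function(object, ...) as.vector(object$residuals)

#' @export
print.bsr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Broken-stick regression\n")
  cat("  change-point c :", format(x$coefficients["c"], digits = digits), "days\n")
  cat("  level at c     :", format(x$coefficients["level_at_c"], digits = digits), "\n")
  cat("  slope before c :", format(x$coefficients["slope_pre"], digits = digits), "per day\n")
  cat("  slope after c  :", format(x$coefficients["slope_post"], digits = digits), "per day\n")
  cat("  points fitted  :", x$n, "  SSE:", format(x$sse, digits = digits),
      " (single line:", format(x$sse_line, digits = digits), ")\n")
  invisible(x)
}

#' Summarise a broken-stick fit
#'
#' @param object a `"bsr"` fit.
#' @param ... unused.
#' @return an object of class `"summary.bsr"` with the coefficient table,
#'   fit diagnostics and the change-point search settings.
#' @export
summary.bsr <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              sse = object$sse, sse_line = object$sse_line,
              n = object$n,
              r2_vs_line = 1 - object$sse / object$sse_line,
              c_search = object$c_search, grid_step = object$grid_step,
              call = object$call)
  class(out) <- "summary.bsr"
  out
}

#' @export
print.summary.bsr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Broken-stick regression\n\nCall:\n  ")
  print(x$call)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nSSE:", format(x$sse, digits = digits),
      "  single-line SSE:", format(x$sse_line, digits = digits),
      "  relative improvement:", format(x$r2_vs_line, digits = digits), "\n")
  cat("Change-point searched on [", x$c_search[1], ",", x$c_search[2],
      "] at step", x$grid_step, "days\n")
  invisible(x)
}

#' Plot a broken-stick fit
#'
#' Draws the fitted series as points, the fitted two-segment line, and an
#' arrow marking the estimated change-point.
#'
#' @param x a `"bsr"` fit.
#' @param arrow draw a vertical arrow at the change-point (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.bsr <- function(x, arrow = TRUE, ...) {
  d <- x$model
  graphics::plot(d$day, d$value, xlab = "day relative to diagnosis",
                 ylab = "concentration", ...)
  tt <- seq(x$day_range[1], x$day_range[2], length.out = 400)
  tt <- sort(c(tt, x$coefficients["c"]))
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  if (arrow) {
    cc <- x$coefficients["c"]
    yv <- predict(x, cc)
    usr <- graphics::par("usr")
    graphics::arrows(cc, yv + 0.2 * (usr[4] - usr[3]), cc,
                     yv + 0.04 * (usr[4] - usr[3]), length = 0.1, col = "blue3")
  }
  invisible(x)
}
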