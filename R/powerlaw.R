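#' Fit the cluster density--area power law y = a * x^b
#'
#' Nonlinear least squares on the linear (untransformed) densities, matching
#' how the seven-day density--area curve is extracted: minimise
#' \eqn{\sum_i (y_i - a x_i^b)^2} by Levenberg--Marquardt. 95% confidence
#' intervals come from the usual local-linearisation covariance at the optimum.
#' A log-space fit (least squares on \eqn{\log y}) is available for diagnostic
#' use but is not the default.
#'
#' @param points data frame with columns `x` (cluster area, um^2, > 0) and `y`
#'   (cluster density, clusters per mm^2 tissue, >= 0); at least 3 points with
#'   distinct `x`.
#' @param start named list/vector with starting values `a` and `b`.
#' @param log_space fit on log densities instead? (Requires all `y > 0`.)
#' @return object of class `power_law_fit`: list with `a`, `b`, `a_ci`, `b_ci`
#'   (95% CIs), `rss`, `n`, and the underlying `nls` fit.
#' @export
fit_power_law <- function(points, start = c(a = 1, b = -0.5), log_space = FALSE) {
  if (!all(c("x", "y") %in% names(points)))
    stop("`points` must have columns `x` and `y`")
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || length(unique(x)) < 3L)
    stop("power-law fit needs at least 3 points with distinct areas")
  if (any(x <= 0)) stop("areas must be positive")
  if (any(y < 0)) stop("densities must be non-negative")
  if (all(y == 0)) stop("degenerate input: all densities are zero")
  start <- as.list(start)
  dat <- data.frame(x = x, y = y)
  fit <- if (log_space) {
    if (any(y == 0)) stop("log-space fit requires strictly positive densities")
    minpack.lm::nlsLM(log(y) ~ log(a) + b * log(x), data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(y ~ a * x^b, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tq <- qt(0.975, df = length(x) - 2L)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 a_ci = unname(est["a"] + c(-1, 1) * tq * se["a"]),
                 b_ci = unname(est["b"] + c(-1, 1) * tq * se["b"]),
                 rss = sum(residuals(fit)^2), n = length(x),
                 log_space = log_space, fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = a * x^b%s\n",
              if (x$log_space) " (log-space)" else ""))
  cat(sprintf("  a = %.6g  (95%% CI %.6g - %.6g)\n", x$a, x$a_ci[1], x$a_ci[2]))
  cat(sprintf("  b = %.6g  (95%% CI %.6g - %.6g)\n", x$b, x$b_ci[1], x$b_ci[2]))
  cat(sprintf("  rss = %.6g over %d points\n", x$rss, x$n))
  invisible(x)
}

#' Evaluate a fitted power law
#'
#' @param fit a `power_law_fit` (or list with elements `a`, `b`).
#' @param x areas, um^2.
#' @return densities `a * x^b`.
#' @export
predict_power_law <- function(fit, x) fit$a * x^fit$b
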