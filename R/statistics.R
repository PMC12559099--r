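# Statistical engine: through-origin regression with t-based inference,
# CI-overlap commutability, bootstrap RMSE intervals, normal fitting of
# residuals, ICC(2,1).

#' Zero-intercept (through-origin) least-squares fit
#'
#' Fits `y = b*x` by least squares: `b = sum(x*y)/sum(x^2)`. One parameter
#' is estimated, so inference uses `n - 1` degrees of freedom:
#' `se = sqrt(SSE/(n-1)/sum(x^2))`, a t-based confidence interval, and a
#' two-sided t test of `b = 0`. This is the regression underlying all
#' scanner calibrations (Slope1, Slope2, Slope1', Slope2') and the
#' CF1-on-CF2 cross-route fit.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`; `sum(x^2) > 0`.
#' @param conf confidence level, default 0.95.
#' @return Object of class `zero_intercept_fit`: list with `slope`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `df`, `conf`.
#' @examples
#' fit_zero_intercept(c(1, 2, 3), c(2.1, 3.9, 6.2))
#' @export
fit_zero_intercept <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) { x <- x[ok]; y <- y[ok] }
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete observations")
  sxx <- sum(x^2)
  if (sxx <= 0) stop("sum(x^2) must be positive (all-zero x)")
  slope <- sum(x * y) / sxx
  df <- n - 1L
  sse <- sum((y - slope * x)^2)
  se <- sqrt(sse / df / sxx)
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  tstat <- if (se > 0) slope / se else if (slope == 0) 0 else Inf * sign(slope)
  structure(list(slope = slope, se = se,
                 ci_low = slope - tq * se, ci_high = slope + tq * se,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 n = n, df = df, conf = conf),
            class = "zero_intercept_fit")
}

#' @export
print.zero_intercept_fit <- function(x, ...) {
  cat(sprintf("Through-origin fit (n = %d): slope %.4f (%.0f%% CI %.4f, %.4f), p = %.3g\n",
              x$n, x$slope, 100 * x$conf, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

ci_of <- function(x) {
  if (inherits(x, "zero_intercept_fit")) return(c(x$ci_low, x$ci_high))
  x <- as.numeric(x)
  if (length(x) != 2L || any(!is.finite(x))) stop("interval must be two finite numbers")
  sort(x)
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval intersection test used for commutability assessment:
#' two scanners' slopes are considered significantly different when their
#' 95% CIs do not overlap. Intervals touching at a single point count as
#' overlapping (conservative toward "not significant").
#'
#' @param ci_a,ci_b length-2 numeric intervals or `zero_intercept_fit`
#'   objects.
#' @return `TRUE` if the closed intervals intersect.
#' @export
ci_overlap <- function(ci_a, ci_b) {
  a <- ci_of(ci_a); b <- ci_of(ci_b)
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' RMSE with a bootstrap confidence interval
#'
#' Root mean square error between observed and estimated values, with a
#' seeded nonparametric bootstrap percentile interval obtained by resampling
#' patients with replacement. The resampling stream is fully defined:
#' `set.seed(seed)` followed by `n_boot` successive draws of
#' `sample.int(n, n, replace = TRUE)`; percentiles use the default
#' `stats::quantile()` type.
#'
#' @param observed,estimated numeric vectors of equal length.
#' @param n_boot number of bootstrap resamples, default 2000.
#' @param seed integer seed for the bootstrap (the global RNG state is
#'   restored afterwards); `NULL` uses the current RNG stream.
#' @param conf confidence level, default 0.95.
#' @return List with `rmse`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
rmse_with_ci <- function(observed, estimated, n_boot = 2000L, seed = NULL,
                         conf = 0.95) {
  observed <- as.numeric(observed); estimated <- as.numeric(estimated)
  if (length(observed) != length(estimated))
    stop("observed and estimated must have equal length")
  n <- length(observed)
  if (n < 1L) stop("need at least 1 observation")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  r <- observed - estimated
  rmse <- sqrt(mean(r^2))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sqrt(mean(r[idx]^2))
    }, numeric(1))
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(rmse = rmse, ci_low = qs[1], ci_high = qs[2], n = n, n_boot = n_boot)
}

# Run `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' Normal fit of residuals with confidence intervals
#'
#' Fits a normal distribution to residuals the way classical toolbox
#' `normfit` routines do: `mu` is the sample mean with a t-based interval;
#' `sigma` is the sample standard deviation (n-1 denominator) with a
#' chi-square interval. `mu` captures bias, `sigma` precision.
#'
#' @param residuals numeric vector, `n >= 2`.
#' @param conf confidence level, default 0.95.
#' @return List with `mu`, `mu_ci_low`, `mu_ci_high`, `sigma`,
#'   `sigma_ci_low`, `sigma_ci_high`, `n`.
#' @export
fit_residual_normal <- function(residuals, conf = 0.95) {
  r <- as.numeric(residuals)
  r <- r[is.finite(r)]
  n <- length(r)
  if (n < 2L) stop("need at least 2 residuals")
  mu <- mean(r)
  s <- stats::sd(r)
  alpha <- 1 - conf
  tq <- stats::qt(1 - alpha / 2, n - 1L)
  if (s == 0) {
    warning("zero-variance residuals: sigma CI is degenerate")
    sig_ci <- c(0, 0)
  } else {
    sig_ci <- sqrt((n - 1L) * s^2 / stats::qchisq(c(1 - alpha / 2, alpha / 2), n - 1L))
  }
  list(mu = mu,
       mu_ci_low = mu - tq * s / sqrt(n), mu_ci_high = mu + tq * s / sqrt(n),
       sigma = s, sigma_ci_low = sig_ci[1], sigma_ci_high = sig_ci[2],
       n = n)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Shrout-Fleiss ICC(2,1) from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1)*MSE + k*(MSC - MSE)/n)`, where MSR, MSC and
#' MSE are the subject, rater and residual mean squares. Absolute agreement:
#' a constant offset between raters lowers the coefficient.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing cells; `>= 2` subjects and `>= 2` raters.
#' @return The ICC(2,1) value.
#' @export
icc_2_1 <- function(ratings) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("ratings must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Residual summary for one estimation method
#'
#' Bundles [rmse_with_ci()] and [fit_residual_normal()] for the residuals
#' `observed - estimated` of one ICG-PDR estimation method: one row of the
#' bias/precision table.
#'
#' @param observed,estimated observed and estimated ICG-PDR (per minute).
#' @param label method label carried into reports.
#' @param n_boot,seed,conf passed to [rmse_with_ci()] /
#'   [fit_residual_normal()].
#' @return Object of class `residual_summary`.
#' @export
summarize_residuals <- function(observed, estimated, label = "",
                                n_boot = 2000L, seed = NULL, conf = 0.95) {
  rm_ <- rmse_with_ci(observed, estimated, n_boot = n_boot, seed = seed, conf = conf)
  nf <- fit_residual_normal(observed - estimated, conf = conf)
  structure(list(method_label = label,
                 rmse = rm_$rmse, rmse_ci_low = rm_$ci_low, rmse_ci_high = rm_$ci_high,
                 mu = nf$mu, mu_ci_low = nf$mu_ci_low, mu_ci_high = nf$mu_ci_high,
                 sigma = nf$sigma, sigma_ci_low = nf$sigma_ci_low,
                 sigma_ci_high = nf$sigma_ci_high,
                 n = rm_$n, n_boot = rm_$n_boot, conf = conf),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("%s (n = %d)\n  RMSE %.3f (%.3f, %.3f)  mu %.3f (%.3f, %.3f)  sigma %.3f (%.3f, %.3f)\n",
              x$method_label, x$n, x$rmse, x$rmse_ci_low, x$rmse_ci_high,
              x$mu, x$mu_ci_low, x$mu_ci_high,
              x$sigma, x$sigma_ci_low, x$sigma_ci_high))
  invisible(x)
}
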