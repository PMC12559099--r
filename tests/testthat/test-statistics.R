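test_that("fit_zero_intercept: closed form, exact fit, grid-search oracle", {
  f <- fit_zero_intercept(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$se, 0)
  expect_equal(c(f$ci_low, f$ci_high), c(2, 2))
  expect_equal(f$p_value, 0)

  # grid-search minimizer of SSE agrees with the closed form
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(20, 2); y <- 1.7 * x + rnorm(20, 0, 0.5)
    f <- fit_zero_intercept(x, y)
    grid <- seq(f$slope - 0.5, f$slope + 0.5, length.out = 20001)
    sse <- vapply(grid, function(b) sum((y - b * x)^2), numeric(1))
    expect_equal(grid[which.min(sse)], f$slope, tolerance = 1e-4)
  }

  expect_error(fit_zero_intercept(c(0, 0), c(1, 2)), "all-zero x")
  expect_error(fit_zero_intercept(1, 2), "at least 2")
})

test_that("fit_zero_intercept is equivariant under scaling of x and y", {
  set.seed(4)
  x <- runif(15, 0.5, 2); y <- -0.17 * x + rnorm(15, 0, 0.02)
  f <- fit_zero_intercept(x, y)
  for (c_ in c(0.25, 3)) {
    fy <- fit_zero_intercept(x, c_ * y)
    expect_equal(c(fy$slope, fy$se, fy$ci_low, fy$ci_high),
                 c_ * c(f$slope, f$se, f$ci_low, f$ci_high))
    fx <- fit_zero_intercept(c_ * x, y)
    expect_equal(c(fx$slope, fx$se, fx$ci_low, fx$ci_high),
                 c(f$slope, f$se, f$ci_low, f$ci_high) / c_)
    expect_equal(fx$p_value, f$p_value)
  }
})

test_that("ci_overlap classifies the published slope CIs and is symmetric", {
  trio <- c(-0.181, -0.165)
  expect_false(ci_overlap(trio, c(-0.135, -0.108)))  # Vida: significant
  expect_true(ci_overlap(trio, c(-0.177, -0.144)))   # Avanto: not
  expect_true(ci_overlap(c(1, 2), c(1, 2)))
  expect_true(ci_overlap(c(0, 1), c(1, 2)))          # touching endpoints overlap

  set.seed(2)
  for (rep in 1:20) {
    a <- sort(rnorm(2)); b <- sort(rnorm(2))
    expect_identical(ci_overlap(a, b), ci_overlap(b, a))
  }
})

test_that("rmse_with_ci: point estimate, permutation invariance, bootstrap oracle", {
  x <- c(0.1, -0.2, 0.3, 0.5)
  expect_equal(rmse_with_ci(x, x, n_boot = 1)$rmse, 0)
  expect_equal(rmse_with_ci(c(1, -1), c(0, 0), n_boot = 1)$rmse, 1)
  expect_error(rmse_with_ci(1:3, 1:2), "equal length")

  set.seed(5)
  obs <- rnorm(30); est <- obs + rnorm(30, 0, 0.3)
  perm <- sample.int(30)
  expect_equal(rmse_with_ci(obs[perm], est[perm], n_boot = 1)$rmse,
               rmse_with_ci(obs, est, n_boot = 1)$rmse)

  # independently coded resampling loop, same seed and stream definition
  r <- obs - est
  res <- rmse_with_ci(obs, est, n_boot = 500, seed = 77)
  set.seed(77)
  boot <- numeric(500)
  for (b in 1:500) {
    idx <- sample.int(30, 30, replace = TRUE)
    boot[b] <- sqrt(sum(r[idx]^2) / 30)
  }
  ci <- unname(quantile(boot, c((1 - 0.95) / 2, 1 - (1 - 0.95) / 2)))
  expect_identical(c(res$ci_low, res$ci_high), ci)

  # reproducible under a fixed seed, global RNG untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(rmse_with_ci(obs, est, n_boot = 50, seed = 9))
  expect_identical(rnorm(1), before)
  expect_identical(rmse_with_ci(obs, est, n_boot = 50, seed = 9)$ci_low,
                   rmse_with_ci(obs, est, n_boot = 50, seed = 9)$ci_low)
})

test_that("fit_residual_normal: degenerate, Monte-Carlo, bootstrap-oracle CIs", {
  expect_warning(f0 <- fit_residual_normal(rep(0.7, 5)), "zero-variance")
  expect_equal(f0$mu, 0.7)
  expect_equal(f0$sigma, 0)
  expect_error(fit_residual_normal(1), "at least 2")

  set.seed(100)
  z <- rnorm(10000)
  f <- fit_residual_normal(z)
  expect_lt(abs(f$mu), 0.03)
  expect_lt(abs(f$sigma - 1), 0.02)
  expect_true(f$mu_ci_low <= f$mu && f$mu <= f$mu_ci_high)

  # chi-square sigma CI vs a seeded parametric bootstrap at n = 50
  set.seed(200)
  r <- rnorm(50, 0, 0.05)
  f <- fit_residual_normal(r)
  set.seed(201)
  sds <- replicate(4000, sd(rnorm(50, f$mu, f$sigma)))
  bci <- unname(quantile(sds, c(0.025, 0.975)))
  width_chi <- f$sigma_ci_high - f$sigma_ci_low
  width_boot <- bci[2] - bci[1]
  expect_lt(abs(width_chi - width_boot) / width_boot, 0.05)
})

test_that("residual summary identity rmse^2 = mu^2 + sigma^2*(n-1)/n", {
  set.seed(6)
  for (rep in 1:10) {
    obs <- rnorm(25); est <- obs + rnorm(25, 0.1, 0.2)
    s <- summarize_residuals(obs, est, n_boot = 1)
    expect_equal(s$rmse^2, s$mu^2 + s$sigma^2 * (s$n - 1) / s$n, tolerance = 1e-12)
  }
})

test_that("icc_2_1 matches an aov mean-squares oracle and penalizes offsets", {
  base <- c(1, 3, 5, 7, 9, 11)
  expect_equal(icc_2_1(cbind(base, base, base)), 1)

  no_off <- icc_2_1(cbind(base, base + rnorm(6, 0, 1e-9)))
  with_off <- icc_2_1(cbind(base, base + 2))
  expect_lt(with_off, no_off)

  set.seed(8)
  m <- matrix(rnorm(18, 5, 2), 6, 3)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:6, 3)), rater = factor(rep(1:3, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (3 - 1) * mse + 3 * (msc - mse) / 6)
  expect_equal(icc_2_1(m), oracle, tolerance = 1e-10)

  m[2, 3] <- NA
  expect_error(icc_2_1(m), "missing")
  expect_error(icc_2_1(matrix(1:3, 3, 1)), ">= 2")
})
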