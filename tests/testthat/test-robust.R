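test_that("OLS fit and leverages", {
  ## exact linear data: zero residuals, exact coefficients
  X <- cbind(1, 1:10, (1:10)^2 / 10)
  y <- as.numeric(X %*% c(2, -1, 0.5))
  fit <- fit_ols(y, X)
  expect_equal(unname(fit$coefficients), c(2, -1, 0.5), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  ## intercept-only model: leverage 1/n everywhere
  fit1 <- fit_ols(rnorm(12), matrix(1, 12, 1))
  expect_equal(fit1$leverage, rep(1 / 12, 12), tolerance = 1e-12)

  ## normal-equations oracle on a seeded n = 189, k = 7 design
  set.seed(61)
  X <- cbind(1, matrix(rnorm(189 * 6), 189, 6))
  y <- rnorm(189)
  fit <- fit_ols(y, X)
  expect_equal(unname(fit$coefficients),
               as.numeric(solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)
  expect_error(fit_ols(y, cbind(X, X[, 2])), "rank")
})

test_that("influence statistics equal literal leave-one-out refits", {
  set.seed(62)
  X <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  y <- as.numeric(X %*% c(1, 2, -1, 0.5)) + rnorm(40)
  fit <- fit_ols(y, X)
  inf <- influence_stats(fit)
  lo <- oracle_influence(y, X)
  expect_equal(inf$rstudent, lo$rstudent, tolerance = 1e-8)
  expect_equal(inf$dffits, lo$dffits, tolerance = 1e-8)
  expect_equal(inf$covratio, lo$covratio, tolerance = 1e-8)

  ## and equal base R's lm-based influence measures
  lmfit <- lm(y ~ X - 1)
  expect_equal(inf$rstudent, unname(rstudent(lmfit)), tolerance = 1e-10)
  expect_equal(inf$dffits, unname(dffits(lmfit)), tolerance = 1e-10)
  expect_equal(inf$covratio, unname(covratio(lmfit)), tolerance = 1e-10)

  ## a gross outlier gets the largest |rstudent| and is flagged
  y2 <- y; y2[7] <- y2[7] + 25
  inf2 <- influence_stats(fit_ols(y2, X))
  expect_identical(which.max(abs(inf2$rstudent)), 7L)
  expect_true(inf2$flag_rstudent[7])

  ## zero residual at a duplicated balanced point: dffits = 0
  Xd <- cbind(1, rep(c(-1, 1), each = 10))
  yd <- as.numeric(Xd %*% c(1, 2))
  infd <- influence_stats(fit_ols(yd + rep(c(-1, 1), 10) * 0, Xd))
  expect_equal(infd$dffits, rep(0, 20))
})

test_that("bisquare tuning constants hit their targets", {
  expect_equal(bisquare_c_breakdown(0.5), 1.5476, tolerance = 1e-3)
  expect_equal(bisquare_c_efficiency(0.95), 4.6851, tolerance = 1e-3)
  ## monotonicity sanity: higher efficiency -> larger constant
  expect_gt(bisquare_c_efficiency(0.99), bisquare_c_efficiency(0.90))
})

test_that("MM estimation: efficiency, robustness, equivariance", {
  set.seed(63)
  n <- 500
  X <- cbind(1, rnorm(n), rnorm(n))
  beta <- c(1, 2, -1)
  y <- as.numeric(X %*% beta) + rnorm(n)

  ## clean Gaussian data: MM close to OLS (3 SE of the OLS fit)
  mm <- fit_mm(y, X, nsamp = 200, seed = 1)
  ols <- fit_ols(y, X)
  se_ols <- ols$sigma * sqrt(diag(ols$XtX_inv))
  expect_true(all(abs(mm$coefficients - ols$coefficients) < 3 * se_ols))
  expect_true(mm$converged)
  expect_true(all(mm$weights >= 0 & mm$weights <= 1))

  ## 10% gross y-outliers at high-leverage x: MM keeps the slope, OLS loses it
  set.seed(64)
  n <- 100
  x <- rnorm(n)
  Xc <- cbind(1, x)
  yc <- 1 + 2 * x
  bad <- order(x, decreasing = TRUE)[1:10]
  yc[bad] <- yc[bad] + 30
  mmc <- fit_mm(yc, Xc, seed = 2)
  olsc <- fit_ols(yc, Xc)
  expect_lt(abs(mmc$coefficients[2] - 2), 0.05)
  expect_gt(abs(olsc$coefficients[2] - 2), 0.5)

  ## equivariance: scaling y scales coefficients and scale
  mm10 <- fit_mm(10 * yc, Xc, seed = 2)
  expect_equal(unname(mm10$coefficients), unname(10 * mmc$coefficients),
               tolerance = 1e-6)
  expect_equal(mm10$scale, 10 * mmc$scale, tolerance = 1e-6)
  ## z statistics are scale-free
  expect_equal(unname(mm10$z), unname(mmc$z), tolerance = 1e-6)

  ## determinism under a fixed seed
  expect_identical(fit_mm(yc, Xc, seed = 5)$coefficients,
                   fit_mm(yc, Xc, seed = 5)$coefficients)

  ## agreement with an independent MM implementation on noisy contaminated
  ## data (the exact-fit case above degenerates rlm's scale to zero)
  set.seed(66)
  yn <- 1 + 2 * x + rnorm(n, sd = 0.2)
  yn[bad] <- yn[bad] + 30
  mmn <- fit_mm(yn, Xc, seed = 2)
  rl <- MASS::rlm(yn ~ x, method = "MM", maxit = 100)
  expect_lt(max(abs(mmn$coefficients - coef(rl))), 0.05)

  expect_error(fit_mm(yc[1:4], Xc[1:4, ]), "n > 2k")
})

test_that("bounded influence: one exploding observation", {
  set.seed(65)
  n <- 80
  x <- rnorm(n)
  X <- cbind(1, x)
  y <- 1 + 2 * x + rnorm(n, sd = 0.5)
  base_mm <- fit_mm(y, X, seed = 3)$coefficients
  y_far <- y; y_far[1] <- 1e6
  far_mm <- fit_mm(y_far, X, seed = 3)$coefficients
  far_ols <- fit_ols(y_far, X)$coefficients
  expect_lt(max(abs(far_mm - base_mm)), 0.5)          # bounded change
  expect_gt(max(abs(far_ols - c(1, 2))), 100)         # OLS diverges
})

test_that("effect classifiers follow the sign/significance rules", {
  expect_identical(classify_demographic_effect(-0.585, TRUE, 1.261, TRUE),
                   "convex")
  expect_identical(classify_demographic_effect(1.250, TRUE, -2.660, TRUE),
                   "concave")
  expect_identical(classify_demographic_effect(-0.5, FALSE, 2.9, TRUE),
                   "positive-ageing")
  expect_identical(classify_demographic_effect(0.1, FALSE, -0.6, TRUE),
                   "negative-ageing")
  expect_identical(classify_demographic_effect(0.3, FALSE, 0.3, FALSE),
                   "none")

  expect_identical(classify_cyclicality(1.735, TRUE), "pro-cyclical")
  expect_identical(classify_cyclicality(-1.078, TRUE), "counter-cyclical")
  expect_identical(classify_cyclicality(0.5, FALSE), "acyclical")
})
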