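test_that("panel generation is seeded, sized and validated", {
  cfg <- test_world()
  p1 <- generate_expenditure_panel(cfg)
  p2 <- generate_expenditure_panel(cfg)
  expect_identical(p1$values, p2$values)          # bit-reproducible

  ## full study calendar and 18 series give a 822 x 18 matrix
  pan <- generate_expenditure_panel(sim_config(seed = 2))
  expect_identical(dim(pan$values), c(822L, 18L))
  expect_identical(colnames(pan$values)[c(1, 18)], c("CCS1", "CCS18"))
  expect_false(anyNA(pan$values))

  ## non-stationary stack rejected naming the period
  A_bad <- diag(1.05, 3)
  expect_error(sim_config(n_series = 3, coefficient_path = list(A_bad)),
               "non-stationary.*constant")
  path <- drift_path(diag(0.2, 3), diag(0.2, 3), 209)
  path[[50]] <- list(diag(1.2, 3))
  cfg_bad <- test_world(n_series = 3)
  cfg_bad$coefficient_path <- path
  expect_error(generate_expenditure_panel(cfg_bad), "period 50")
})

test_that("zero-coefficient panel has identity covariance within 3 SE", {
  N <- 4
  cfg <- sim_config(n_series = N, coefficient_path = list(matrix(0, N, N)),
                    innovation_cov = diag(N), intercept = 0, seed = 5)
  x <- generate_expenditure_panel(cfg)$values      # 822 x 4 iid N(0, I)
  T_ <- nrow(x)
  S <- crossprod(scale(x, center = TRUE, scale = FALSE)) / (T_ - 1)
  se_var <- sqrt(2 / (T_ - 1))                     # SE of a unit variance
  se_cov <- sqrt(1 / (T_ - 1))                     # SE of a zero covariance
  expect_true(all(abs(diag(S) - 1) < 3 * se_var))
  off <- S[upper.tri(S)]
  expect_true(all(abs(off) < 3 * se_cov))
})

test_that("simulated moments converge to the VAR's implied moments", {
  ## AR(1)-style VAR: implied unconditional covariance solves the discrete
  ## Lyapunov equation; check via a long sample
  A <- matrix(c(0.5, 0.1, 0.2, 0.3), 2, 2)
  Sig <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  cfg <- sim_config(n_series = 2, coefficient_path = list(A),
                    innovation_cov = Sig, intercept = 0, seed = 9,
                    calendar = make_calendar("2000-01-01", "2150-12-31"))
  x <- generate_expenditure_panel(cfg)$values
  ## Lyapunov by series summation (independent of package code)
  V <- Sig; Ak <- A
  for (k in 1:200) { V <- V + Ak %*% Sig %*% t(Ak); Ak <- Ak %*% A }
  S <- stats::cov(x)
  expect_lt(max(abs(S - V)), 3 * max(abs(V)) * sqrt(2 / nrow(x)) * 3)
})

test_that("covariates respect their construction", {
  cfg <- test_world()

  ## zero cycle noise -> HP cycle of every covariate ~ 0
  quiet <- lapply(c("young_dep", "old_dep", "leading_index", "medical_price",
                    "primary_care_share", "wage_growth",
                    "productivity_growth", "labor_share"),
                  function(nm) list(sd = 0))
  names(quiet) <- c("young_dep", "old_dep", "leading_index", "medical_price",
                    "primary_care_share", "wage_growth",
                    "productivity_growth", "labor_share")
  cfg$covariates <- quiet
  cov0 <- generate_covariates(cfg)
  for (nm in c("young_dep", "old_dep", "leading_index"))
    expect_lt(max(abs(hp_filter(cov0[[nm]], 14400)$cycle)), 1e-6)

  ## equal wage and productivity growth -> baumol identically 0
  cfg2 <- test_world()
  cfg2$covariates <- list(
    wage_growth = list(from = 0.003, to = 0.001, sd = 0),
    productivity_growth = list(from = 0.003, to = 0.001, sd = 0))
  expect_equal(max(abs(generate_covariates(cfg2)$baumol)), 0)

  ## demographic transition: old ratio rises, young falls (trend design)
  cov <- generate_covariates(cfg)   # noiseless via quiet config
  expect_gt(cov$old_dep[nrow(cov)], cov$old_dep[1])
  expect_lt(cov$young_dep[nrow(cov)], cov$young_dep[1])

  ## determinism and bounds
  cfg3 <- test_world()
  expect_identical(generate_covariates(cfg3), generate_covariates(cfg3))
  cv <- generate_covariates(cfg3)
  expect_true(all(cv$primary_care_share >= 0 & cv$primary_care_share <= 1))

  ## non-positive labor share -> invalid config naming the month
  cfg4 <- test_world()
  cfg4$covariates <- list(labor_share = list(from = 0.01, to = -0.01, sd = 0))
  expect_error(generate_covariates(cfg4), "labor share")
})

test_that("true_connectedness computes ground truth through the gfevd path", {
  ## diagonal coefficients + diagonal innovations: no spillover at all
  tab <- true_connectedness(diag(c(0.5, 0.2, 0.4)), diag(3), horizon = 10)
  expect_equal(tab$tci, 0, tolerance = 1e-12)
  expect_equal(unname(tab$ntdci), rep(0, 3))

  ## zero-sum identity on an arbitrary valid input
  A <- matrix(c(0.3, 0.15, -0.1, 0.4), 2, 2)
  S <- matrix(c(1, 0.4, 0.4, 2), 2, 2)
  tab2 <- true_connectedness(A, S, horizon = 10)
  expect_equal(sum(tab2$ntdci), 0, tolerance = 1e-10)

  ## matches the brute-force MA-accumulation oracle
  phi_oracle <- oracle_gfevd(A, S, H = 10)
  expect_equal(unname(tab2$fevd), phi_oracle, tolerance = 1e-10)

  expect_error(true_connectedness(diag(1.01, 2), diag(2)), "non-stationary")
})
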