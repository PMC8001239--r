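#' Deflate an expenditure series to real per-capita terms
#'
#' Divides nominal expenditure by population and rescales by a price index so
#' that values are expressed in prices of a chosen base period:
#' `out[t] = (expenditure[t] / population[t]) * price[base] / price[t]`.
#'
#' @param expenditure Numeric vector of nominal expenditure.
#' @param population Numeric vector (or scalar) of population counts, > 0.
#' @param price_index Numeric vector (or scalar) of price-index levels, > 0.
#' @param base_period Integer position in `price_index` taken as the base.
#' @return Numeric vector of real per-capita expenditure, same length.
#' @export
deflate_per_capita <- function(expenditure, population, price_index,
                               base_period) {
  n <- length(expenditure)
  check_numeric_vector(expenditure, "expenditure")
  population <- rep_len(as.numeric(population), n)
  price_index <- rep_len(as.numeric(price_index), n)
  bad <- which(population <= 0)
  if (length(bad))
    stop_input("non-positive population at period %d", bad[1])
  bad <- which(price_index <= 0)
  if (length(bad))
    stop_input("non-positive price index at period %d", bad[1])
  if (!is.numeric(base_period) || base_period < 1 || base_period > n)
    stop_input("base_period must index a period 1..%d", n)
  (expenditure / population) * price_index[base_period] / price_index
}

#' Repeated first differences
#'
#' @param x Numeric vector.
#' @param order Number of times to difference (>= 1).
#' @return Vector of length `length(x) - order`.
#' @export
difference <- function(x, order = 1L) {
  check_numeric_vector(x, "x", min_len = 2L)
  if (order < 1) stop_input("order must be >= 1")
  if (order >= length(x))
    stop_input("order (%d) must be smaller than series length (%d)",
               order, length(x))
  diff(x, differences = order)
}

#' Hodrick-Prescott trend/cycle decomposition
#'
#' Extracts the smooth trend \eqn{\tau} minimizing
#' \eqn{\sum_t (y_t - \tau_t)^2 + \lambda \sum_t (\Delta^2 \tau_t)^2}
#' by solving the sparse pentadiagonal normal equations
#' \eqn{(I + \lambda D'D)\tau = y}.  The cycle is `y - trend`, so trend plus
#' cycle reproduces the input exactly.  `lambda = 14400` is the conventional
#' choice for monthly data (1600 for quarterly).
#'
#' @param x Numeric series, length >= 4, no missing values.
#' @param lambda Smoothing penalty, > 0.
#' @return Object of class `trend_cycle`: list with `trend`, `cycle`,
#'   `lambda`.
#' @export
hp_filter <- function(x, lambda = 14400) {
  check_numeric_vector(x, "x", min_len = 4L)
  if (!is.numeric(lambda) || lambda <= 0) stop_input("lambda must be > 0")
  n <- length(x)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2),
                                           rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  trend <- as.numeric(Matrix::solve(A, x))
  structure(list(trend = trend, cycle = x - trend, lambda = lambda),
            class = "trend_cycle")
}

#' @export
print.trend_cycle <- function(x, ...) {
  cat(sprintf("<trend_cycle> n = %d, lambda = %g, cycle sd = %.4g\n",
              length(x$trend), x$lambda, stats::sd(x$cycle)))
  invisible(x)
}

## MacKinnon (2010) response-surface coefficients for the 5% tau critical
## value: crit = b0 + b1/T + b2/T^2 + b3/T^3.
.pp_crit_5pct <- function(spec, T_) {
  b <- switch(spec,
    none     = c(-1.94100, -0.2686, -3.365, 31.223),
    constant = c(-2.86154, -2.8903, -4.234, -40.040),
    trend    = c(-3.41049, -4.3904, -9.036, -45.374))
  b[1] + b[2] / T_ + b[3] / T_^2 + b[4] / T_^3
}

#' Phillips-Perron unit-root test
#'
#' Estimates the first-order autoregression `y_t = d_t + rho * y_{t-1} + u_t`
#' (deterministics `d_t` per `deterministic`) and corrects the
#' Dickey-Fuller statistics for serial correlation in `u_t` nonparametrically
#' with a Bartlett-kernel (Newey-West) long-run variance.  With
#' `bandwidth = 0` the long-run and short-run variances coincide and `z_tau`
#' reduces to the plain Dickey-Fuller t-statistic.  The 5% rejection decision
#' uses MacKinnon response-surface critical values.
#'
#' @param x Numeric series, length >= 20, not constant.
#' @param deterministic Deterministic specification: `"constant"` (default),
#'   `"trend"` (constant + linear trend), or `"none"`.
#' @param bandwidth Lag truncation for the Newey-West correction; default
#'   `floor(4 * (T/100)^(2/9))` (the Newey-West automatic rule).
#' @return Object of class `pp_result`: `z_tau`, `z_rho`, `bandwidth`,
#'   `deterministic_spec`, `crit_5pct`, `reject_5pct`, `n`.
#' @export
pp_test <- function(x, deterministic = c("constant", "trend", "none"),
                    bandwidth = NULL) {
  deterministic <- match.arg(deterministic)
  check_numeric_vector(x, "x", min_len = 20L)
  if (stats::sd(x) == 0)
    stop_input("constant series: unit-root regression is degenerate")
  n <- length(x)
  y <- x[-1]
  ylag <- x[-n]
  T_ <- n - 1L
  X <- switch(deterministic,
              none = cbind(ylag),
              constant = cbind(1, ylag),
              trend = cbind(1, seq_len(T_), ylag))
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) stop_input("degenerate unit-root regression (rank < %d)", k)
  beta <- qr.coef(qrX, y)
  rho <- unname(beta[k])
  u <- as.numeric(y - X %*% beta)
  s2 <- sum(u^2) / (T_ - k)                  # OLS residual variance
  XtX_inv <- chol2inv(qr.R(qrX))
  se_rho <- sqrt(s2 * XtX_inv[k, k])
  t_df <- (rho - 1) / se_rho

  if (is.null(bandwidth)) bandwidth <- floor(4 * (T_ / 100)^(2 / 9))
  bandwidth <- as.integer(bandwidth)
  if (bandwidth < 0) stop_input("bandwidth must be >= 0")
  gamma0 <- sum(u^2) / T_
  lam2 <- gamma0
  if (bandwidth > 0) {
    for (l in seq_len(bandwidth)) {
      gl <- sum(u[(l + 1):T_] * u[1:(T_ - l)]) / T_
      lam2 <- lam2 + 2 * (1 - l / (bandwidth + 1)) * gl
    }
  }
  if (lam2 <= 0) lam2 <- gamma0   # kernel guard; Bartlett keeps lam2 > 0

  z_tau <- sqrt(gamma0 / lam2) * t_df -
    (lam2 - gamma0) * T_ * se_rho / (2 * sqrt(lam2) * sqrt(s2))
  z_rho <- T_ * (rho - 1) - (T_^2 * se_rho^2 / s2) * (lam2 - gamma0) / 2

  crit <- .pp_crit_5pct(deterministic, T_)
  structure(
    list(z_tau = z_tau, z_rho = z_rho, bandwidth = bandwidth,
         deterministic_spec = deterministic,
         crit_5pct = crit, reject_5pct = z_tau < crit, n = n),
    class = "pp_result"
  )
}

#' @export
print.pp_result <- function(x, ...) {
  cat(sprintf(
    "Phillips-Perron test (%s, bandwidth %d): Z_tau = %.3f, Z_rho = %.3f\n",
    x$deterministic_spec, x$bandwidth, x$z_tau, x$z_rho))
  cat(sprintf("5%% critical value %.3f: %s the unit root\n", x$crit_5pct,
              if (x$reject_5pct) "reject" else "do not reject"))
  invisible(x)
}

## Apply a named preprocessing recipe entry to one series.
## transform in {"hp_cycle", "difference", "none"}; differencing pads with a
## leading NA so columns stay aligned (callers drop incomplete rows).
apply_transform <- function(x, transform, lambda = 14400) {
  switch(transform,
         hp_cycle = hp_filter(x, lambda)$cycle,
         difference = c(NA_real_, difference(x, 1L)),
         none = x,
         stop_input("unknown transform '%s' (use hp_cycle/difference/none)",
                    transform))
}
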