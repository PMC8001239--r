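#' Construct a VAR parameter set
#'
#' @param A List of p coefficient matrices (N x N), lag 1 first; a single
#'   matrix is treated as a VAR(1) stack.
#' @param Sigma Innovation covariance (N x N, symmetric PSD).
#' @param intercept Optional intercept vector (default zero).
#' @return Object of class `var_params` with fields `p`, `n_series`,
#'   `intercept`, `A`, `Sigma`, `companion_radius`.
#' @export
var_params <- function(A, Sigma, intercept = NULL) {
  if (is.matrix(A)) A <- list(A)
  if (!length(A) || !all(vapply(A, is.matrix, TRUE)))
    stop_input("A must be a matrix or list of square matrices")
  N <- nrow(A[[1]])
  for (Ai in A)
    if (nrow(Ai) != N || ncol(Ai) != N)
      stop_input("all coefficient matrices must be %d x %d", N, N)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != N || ncol(Sigma) != N)
    stop_input("Sigma must be %d x %d", N, N)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(abs(Sigma), 1))
    stop_input("Sigma must be symmetric")
  ev <- eigen(symmetrize(Sigma), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop_input("Sigma must be positive semi-definite")
  intercept <- if (is.null(intercept)) rep(0, N) else rep_len(intercept, N)
  structure(
    list(p = length(A), n_series = N, intercept = intercept,
         A = A, Sigma = symmetrize(Sigma),
         companion_radius = spectral_radius(companion_matrix(A))),
    class = "var_params"
  )
}

#' Companion matrix of a VAR coefficient stack
#' @param A List of p coefficient matrices (N x N).
#' @return The (Np x Np) companion matrix.
#' @export
companion_matrix <- function(A) {
  if (is.matrix(A)) A <- list(A)
  N <- nrow(A[[1]]); p <- length(A)
  C <- matrix(0, N * p, N * p)
  C[seq_len(N), ] <- do.call(cbind, A)
  if (p > 1)
    C[(N + 1):(N * p), seq_len(N * (p - 1))] <- diag(N * (p - 1))
  C
}

is_stationary <- function(A, tol = 1 - 1e-8) {
  spectral_radius(companion_matrix(A)) < tol
}

#' @export
print.var_params <- function(x, ...) {
  cat(sprintf("<var_params> N = %d, p = %d, companion radius = %.3f\n",
              x$n_series, x$p, x$companion_radius))
  invisible(x)
}

#' Fit a constant-parameter VAR by equation-wise least squares
#'
#' Ordinary least squares of each series on an intercept and p lags of all
#' series; the innovation covariance uses residual cross-products with a
#' degrees-of-freedom correction.  Serves as the static limit (no forgetting)
#' of the time-varying estimator.
#'
#' @param panel Numeric matrix (T x N) or [generate_expenditure_panel()]
#'   output.
#' @param p Lag order.
#' @return A [var_params()] object with `residuals` and `nobs` attached.
#' @export
fit_ols_var <- function(panel, p = 1L) {
  Y <- panel_values(panel)
  N <- ncol(Y); T_ <- nrow(Y)
  if (p < 1) stop_input("p must be >= 1")
  if (T_ <= N * p + 1)
    stop_input("need T > N*p + 1 observations (T = %d, N = %d, p = %d)",
               T_, N, p)
  XY <- var_design(Y, p)
  qrX <- qr(XY$X)
  if (qrX$rank < ncol(XY$X))
    stop_input("rank-deficient regressor matrix in VAR fit")
  B <- qr.coef(qrX, XY$Y)            # k x N, k = 1 + N*p
  resid <- XY$Y - XY$X %*% B
  k <- ncol(XY$X)
  Sigma <- crossprod(resid) / (nrow(XY$Y) - k)
  out <- var_params(A = split_coef(B, N, p), Sigma = Sigma,
                    intercept = B[1, ])
  out$residuals <- resid
  out$nobs <- nrow(XY$Y)
  out
}

## Lagged design: Y_t on [1, y_{t-1}, ..., y_{t-p}].
var_design <- function(Y, p) {
  T_ <- nrow(Y); N <- ncol(Y)
  X <- matrix(1, T_ - p, 1 + N * p)
  for (l in seq_len(p))
    X[, (2 + N * (l - 1)):(1 + N * l)] <- Y[(p - l + 1):(T_ - l), , drop = FALSE]
  list(Y = Y[(p + 1):T_, , drop = FALSE], X = X)
}

## Inverse of var_design coefficient layout: k x N matrix -> list of A_l.
split_coef <- function(B, N, p) {
  lapply(seq_len(p), function(l)
    t(B[(2 + N * (l - 1)):(1 + N * l), , drop = FALSE]))
}

#' Moving-average (impulse-response) coefficients of a VAR
#'
#' Recursion \eqn{\Psi_0 = I}, \eqn{\Psi_h = \sum_{j=1}^{\min(h,p)} A_j
#' \Psi_{h-j}}.
#'
#' @param params A [var_params()] object (or list of A matrices).
#' @param horizon Highest MA order to return (>= 1).
#' @return List of `horizon + 1` matrices, \eqn{\Psi_0 \ldots \Psi_H}.
#' @export
ma_coefficients <- function(params, horizon) {
  A <- if (inherits(params, "var_params")) params$A else params
  if (is.matrix(A)) A <- list(A)
  if (horizon < 1) stop_input("horizon must be >= 1")
  N <- nrow(A[[1]]); p <- length(A)
  Psi <- vector("list", horizon + 1)
  Psi[[1]] <- diag(N)
  for (h in seq_len(horizon)) {
    M <- matrix(0, N, N)
    for (j in seq_len(min(h, p)))
      M <- M + A[[j]] %*% Psi[[h - j + 1]]
    Psi[[h + 1]] <- M
  }
  Psi
}

## Simulate a (possibly time-varying) VAR path.  A_path is a single stack or
## a list of stacks of length n (one per retained period); burn-in uses the
## first stack.  Deterministic given the RNG state of the caller.
simulate_var_path <- function(A_path, Sigma, n, intercept = 0, burn = 200L) {
  ## normalize: path = list over time of stacks (each stack = list of A_l)
  if (is.matrix(A_path)) A_path <- list(A_path)
  if (is.matrix(A_path[[1]])) {            # one stack for all periods
    stack0 <- A_path
    path <- NULL
  } else {
    if (length(A_path) != n)
      stop_input("time-varying coefficient path must have length %d", n)
    stack0 <- A_path[[1]]
    path <- A_path
  }
  N <- nrow(stack0[[1]]); p <- length(stack0)
  intercept <- rep_len(intercept, N)
  L <- chol(symmetrize(as.matrix(Sigma)))
  total <- n + burn
  E <- matrix(stats::rnorm(total * N), total, N) %*% L
  Ylag <- matrix(0, p, N)                  # most recent first
  out <- matrix(0, n, N)
  for (t in seq_len(total)) {
    stack <- if (is.null(path) || t <= burn) stack0 else path[[t - burn]]
    y <- intercept + E[t, ]
    for (l in seq_len(p)) y <- y + stack[[l]] %*% Ylag[l, ]
    y <- as.numeric(y)
    if (p > 1) Ylag[2:p, ] <- Ylag[1:(p - 1), , drop = FALSE]
    Ylag[1, ] <- y
    if (t > burn) out[t - burn, ] <- y
  }
  out
}

## Extract the data matrix from a panel or plain matrix.
panel_values <- function(panel) {
  if (inherits(panel, "expenditure_panel")) return(panel$values)
  m <- as.matrix(panel)
  if (!is.numeric(m)) stop_input("panel must be numeric")
  if (anyNA(m)) stop_input("panel contains missing values")
  m
}
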