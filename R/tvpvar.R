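#' Time-varying-parameter VAR by Kalman filtering with forgetting factors
#'
#' Estimates a VAR whose coefficients and innovation covariance evolve over
#' time, avoiding rolling windows.  Writing the measurement equation as
#' \eqn{y_t = (I_N \otimes x_t') \beta_t + \epsilon_t} with
#' \eqn{x_t = (1, y_{t-1}', \ldots, y_{t-p}')'} and random-walk state
#' \eqn{\beta_t = \beta_{t-1} + u_t}, the filter replaces an explicit state
#' noise covariance by forgetting: the one-step prediction covariance is
#' \eqn{P_{t|t-1} = P_{t-1|t-1} / \kappa_1}, and the innovation covariance is
#' updated by an exponentially weighted moving average of one-step prediction
#' errors, \eqn{\Sigma_t = \kappa_2 \Sigma_{t-1} + (1 - \kappa_2) e_t e_t'}.
#' With \eqn{\kappa_1 = \kappa_2 = 1} the recursion is recursive least
#' squares and (under a diffuse prior) reproduces the full-sample OLS VAR at
#' the final period.
#'
#' The Joseph-form covariance update plus symmetrization keeps every
#' covariance symmetric PSD; any residual negative eigenvalue is clipped with
#' a warning.
#'
#' @param panel Numeric matrix (T x N) or `expenditure_panel`.
#' @param p Lag order (default 1; see [select_var_order()]).
#' @param kappa1 Coefficient forgetting factor in (0, 1], default 0.99.
#' @param kappa2 Covariance (EWMA) forgetting factor in (0, 1], default 0.96.
#' @param prior `"ols"` (default): prior mean/covariance from an OLS fit on
#'   the first `prior_fraction` of the sample, then filtering over the full
#'   sample (the customary forgetting-factor initialization); `"diffuse"`:
#'   an exact information start — least squares on the smallest full-rank
#'   leading block with identity innovation covariance, filtering from the
#'   next observation on, so that kappa = 1 is exact recursive least squares
#'   (the leading block's states repeat the initial state).
#' @param prior_fraction Fraction of the sample used for the training-sample
#'   prior (default 0.1).
#' @param store_uncertainty Keep the full coefficient-uncertainty matrix at
#'   every period?  Default `FALSE` (only the final-period matrix is kept;
#'   the full path is O(T (Nk)^2) memory).
#' @return Object of class `tvpvar_states`: list with arrays `B`
#'   (k x N x T_eff coefficient matrices, intercept row first), `Sigma`
#'   (N x N x T_eff), the final uncertainty matrix `P_final` (plus
#'   `P` list if requested), and metadata (`p`, `kappa1`, `kappa2`,
#'   `series_ids`, `dates`).
#' @export
fit_tvp_var <- function(panel, p = 1L, kappa1 = 0.99, kappa2 = 0.96,
                        prior = c("ols", "diffuse"), prior_fraction = 0.1,
                        store_uncertainty = FALSE) {
  prior <- match.arg(prior)
  Y <- panel_values(panel)
  if (!all(is.finite(Y))) stop_input("panel contains non-finite values")
  if (kappa1 <= 0 || kappa1 > 1 || kappa2 <= 0 || kappa2 > 1)
    stop_input("forgetting factors must lie in (0, 1]")
  N <- ncol(Y); T_ <- nrow(Y); p <- as.integer(p)
  if (T_ <= N * p + 1) stop_input("too few observations for p = %d", p)
  XY <- var_design(Y, p)
  X <- XY$X; Yt <- XY$Y
  k <- ncol(X); Teff <- nrow(Yt); dim_state <- N * k

  if (prior == "ols") {
    n0 <- max(ceiling(prior_fraction * Teff), k + N + 2)
    if (n0 > Teff) stop_input("prior window exceeds sample")
    qr0 <- qr(X[seq_len(n0), , drop = FALSE])
    if (qr0$rank < k)
      stop_input("panel not full rank on the training window (first %d obs)", n0)
    B0 <- qr.coef(qr0, Yt[seq_len(n0), , drop = FALSE])
    R0 <- Yt[seq_len(n0), , drop = FALSE] - X[seq_len(n0), , drop = FALSE] %*% B0
    Sigma0 <- symmetrize(crossprod(R0) / max(n0 - k, 1))
    XtX0_inv <- chol2inv(qr.R(qr0))
    b <- as.numeric(B0)                         # vec(B0), equations stacked
    P <- kronecker(Sigma0, XtX0_inv)
    t_start <- 1L
  } else {
    ## exact information start on the smallest full-rank leading block
    m <- k
    repeat {
      if (m > Teff - 1) stop_input("panel too short for a diffuse start")
      qr0 <- qr(X[seq_len(m), , drop = FALSE])
      if (qr0$rank == k) break
      m <- m + 1L
    }
    B0 <- qr.coef(qr0, Yt[seq_len(m), , drop = FALSE])
    XtX0_inv <- chol2inv(qr.R(qr0))
    Sigma0 <- diag(N)
    b <- as.numeric(B0)
    P <- kronecker(Sigma0, XtX0_inv)
    t_start <- m + 1L
  }
  Sig <- Sigma0

  Barr <- array(NA_real_, c(k, N, Teff))
  Sarr <- array(NA_real_, c(N, N, Teff))
  Plist <- if (store_uncertainty) vector("list", Teff) else NULL
  if (t_start > 1L) {
    for (t in seq_len(t_start - 1L)) {
      Barr[, , t] <- matrix(b, k, N)
      Sarr[, , t] <- Sig
      if (store_uncertainty) Plist[[t]] <- P
    }
  }

  for (t in seq.int(t_start, Teff)) {
    x <- X[t, ]
    Pp <- P / kappa1
    Bmat <- matrix(b, k, N)
    e <- Yt[t, ] - as.numeric(crossprod(Bmat, x))   # prediction error
    ## Z Pp and Z Pp Z' exploiting Z = I_N (x) x'
    ZP <- matrix(0, N, dim_state)                   # rows: x' P[block j, ]
    for (j in seq_len(N))
      ZP[j, ] <- as.numeric(x %*% matrix(Pp[((j - 1) * k + 1):(j * k), ],
                                         k, dim_state))
    ZPZ <- matrix(0, N, N)
    for (j in seq_len(N))
      ZPZ[, j] <- ZP[, ((j - 1) * k + 1):(j * k)] %*% x
    S <- symmetrize(ZPZ) + Sig
    Sc <- tryCatch(chol(S), error = function(err)
      stop_input("numerically singular update at period %d", t))
    K <- t(backsolve(Sc, forwardsolve(t(Sc), ZP)))  # Pp Z' S^{-1}, dim_state x N
    b <- b + as.numeric(K %*% e)
    ## Joseph form expanded with K = Pp Z' S^{-1}:
    ## (I-KZ)Pp(I-KZ)' + K Sig K' = Pp - K(ZPp) - (K ZPp)' + K S K'
    KZP <- K %*% ZP
    P <- Pp - KZP - t(KZP) + K %*% S %*% t(K)
    P <- symmetrize(P)
    dP <- diag(P)
    if (any(dP < 0)) P <- psd_floor(P, sprintf("P at period %d", t))
    Sig <- symmetrize(kappa2 * Sig + (1 - kappa2) * tcrossprod(e))
    Barr[, , t] <- matrix(b, k, N)
    Sarr[, , t] <- Sig
    if (store_uncertainty) Plist[[t]] <- P
  }

  ids <- colnames(Y) %||% paste0("V", seq_len(N))
  dates <- if (inherits(panel, "expenditure_panel"))
    panel$calendar$week_starts[(p + 1):T_] else seq_len(Teff) + p
  structure(
    list(B = Barr, Sigma = Sarr, P_final = P, P = Plist,
         p = p, k = k, n_series = N, n_periods = Teff,
         kappa1 = kappa1, kappa2 = kappa2, prior = prior,
         series_ids = ids, dates = dates),
    class = "tvpvar_states"
  )
}

#' @export
print.tvpvar_states <- function(x, ...) {
  cat(sprintf(
    "<tvpvar_states> N = %d, p = %d, %d periods, kappa1 = %.3f, kappa2 = %.3f\n",
    x$n_series, x$p, x$n_periods, x$kappa1, x$kappa2))
  invisible(x)
}

## Per-period parameters as a var_params-compatible stack.
state_params <- function(states, t) {
  B <- states$B[, , t]
  if (is.null(dim(B))) B <- matrix(B, states$k, states$n_series)
  Sig <- symmetrize(states$Sigma[, , t])
  dimnames(Sig) <- list(states$series_ids, states$series_ids)
  list(A = split_coef(B, states$n_series, states$p),
       Sigma = Sig, intercept = B[1, ])
}

#' Select the VAR lag order by BIC
#'
#' Fits constant-parameter VARs for `p = 1..p_max` and returns the order
#' minimizing the Bayesian information criterion computed from the Gaussian
#' log-likelihood on the common estimation sample.
#'
#' @param panel Data matrix or `expenditure_panel`.
#' @param p_max Largest order considered (default 4).
#' @return Integer lag order.
#' @export
select_var_order <- function(panel, p_max = 4L) {
  Y <- panel_values(panel)
  N <- ncol(Y); T_ <- nrow(Y)
  bic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    if (T_ - p_max <= N * p + 1) break
    XY <- var_design(Y, p)
    keep <- (p_max - p + 1):nrow(XY$Y)       # common sample across orders
    Xp <- XY$X[keep, , drop = FALSE]; Yp <- XY$Y[keep, , drop = FALSE]
    B <- qr.coef(qr(Xp), Yp)
    R <- Yp - Xp %*% B
    n <- nrow(Yp)
    Sig <- crossprod(R) / n
    bic[p] <- log(det(Sig)) + log(n) * (ncol(Xp) * N) / n
  }
  which.min(bic)
}
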