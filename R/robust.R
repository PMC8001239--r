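## Tukey bisquare family.  rho is normalized to max 1 so the M-scale
## equation reads mean(rho(r/s)) = b with b = breakdown point.

rho_bisq <- function(u, c) {
  v <- pmin(abs(u) / c, 1)
  1 - (1 - v^2)^3
}

psi_bisq <- function(u, c) {
  out <- u * (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

## psi'(u)
dpsi_bisq <- function(u, c) {
  v <- (u / c)^2
  out <- (1 - v) * (1 - 5 * v)
  out[abs(u) > c] <- 0
  out
}

## weight w(u) = psi(u)/u (limit 1 at 0 after scaling; constants cancel in WLS)
wt_bisq <- function(u, c) {
  out <- (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

#' Bisquare tuning constants for a target breakdown point or efficiency
#'
#' `bisquare_c_breakdown(0.5)` returns the S-stage constant (~1.5476) solving
#' `E[rho_c(Z)] = breakdown` for standard normal Z; `bisquare_c_efficiency
#' (0.95)` returns the M-stage constant (~4.685) attaining the requested
#' Gaussian efficiency `(E psi')^2 / E psi^2`.
#'
#' @param breakdown,efficiency Targets in (0, 1).
#' @return The tuning constant.
#' @export
bisquare_c_breakdown <- function(breakdown = 0.5) {
  if (breakdown <= 0 || breakdown >= 1) stop_input("breakdown must be in (0,1)")
  f <- function(cc)
    stats::integrate(function(z) rho_bisq(z, cc) * stats::dnorm(z),
                     -Inf, Inf)$value - breakdown
  stats::uniroot(f, c(0.2, 20), tol = 1e-10)$root
}

#' @rdname bisquare_c_breakdown
#' @export
bisquare_c_efficiency <- function(efficiency = 0.95) {
  if (efficiency <= 0 || efficiency >= 1)
    stop_input("efficiency must be in (0,1)")
  eff <- function(cc) {
    a <- stats::integrate(function(z) psi_bisq(z, cc)^2 * stats::dnorm(z),
                          -Inf, Inf)$value
    b <- stats::integrate(function(z) dpsi_bisq(z, cc) * stats::dnorm(z),
                          -Inf, Inf)$value
    b^2 / a
  }
  stats::uniroot(function(cc) eff(cc) - efficiency, c(1, 30),
                 tol = 1e-10)$root
}

## M-scale: solve mean(rho(r/s)) = b for s by fixed point iteration.
mscale <- function(r, c, b = 0.5, tol = 1e-10, max_it = 200L) {
  r <- r[is.finite(r)]
  s <- stats::median(abs(r)) / 0.6745
  if (s == 0) {
    ## more than half the residuals are zero: scale collapses
    return(0)
  }
  for (i in seq_len(max_it)) {
    m <- mean(rho_bisq(r / s, c))
    s_new <- s * sqrt(m / b)
    if (abs(s_new - s) <= tol * s) return(s_new)
    s <- s_new
  }
  s
}

#' Ordinary least squares with hat-matrix leverages
#'
#' Minimal OLS fit carrying everything the influence diagnostics and the
#' MM covariance need: coefficients, residuals, leverages, and `(X'X)^{-1}`.
#'
#' @param y Response vector.
#' @param X Design matrix (including the intercept column if wanted).
#' @return Object of class `ols_fit`: `coefficients`, `residuals`, `fitted`,
#'   `leverage`, `sigma`, `df_residual`, `XtX_inv`, `n`, `k`, `X`, `y`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  check_numeric_vector(y, "y", min_len = 2L)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop_input("y and X are misaligned (%d vs %d rows)",
                                 length(y), n)
  if (n <= k) stop_input("need more observations (%d) than parameters (%d)",
                         n, k)
  qrX <- qr(X)
  if (qrX$rank < k) stop_input("rank-deficient design matrix")
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  Q <- qr.Q(qrX)
  lev <- rowSums(Q^2)
  s2 <- sum(resid^2) / (n - k)
  structure(
    list(coefficients = beta, residuals = resid, fitted = fitted,
         leverage = lev, sigma = sqrt(s2), df_residual = n - k,
         XtX_inv = chol2inv(qr.R(qrX)), n = n, k = k, X = X, y = y),
    class = "ols_fit"
  )
}

#' Leave-one-out influence diagnostics
#'
#' Computes, per observation, the externally studentized residual, DFFITS
#' (scaled change in the fitted value when the observation is dropped) and
#' COVRATIO (ratio of coefficient-covariance determinants without vs. with
#' the observation), with outlier flags at the textbook thresholds
#' `|RStudent| > 2`, `|DFFITS| > 2 sqrt(k/n)`, `|COVRATIO - 1| > 3k/n`
#' (all configurable).
#'
#' @param fit A [fit_ols()] result.
#' @param rstudent_cut,dffits_cut,covratio_cut Flag thresholds; `NULL` uses
#'   the defaults above.
#' @return Data frame (class `influence_table`) with columns `obs`,
#'   `rstudent`, `dffits`, `covratio`, `flag_rstudent`, `flag_dffits`,
#'   `flag_covratio`, `flagged`; thresholds stored as attributes.
#' @export
influence_stats <- function(fit, rstudent_cut = 2, dffits_cut = NULL,
                            covratio_cut = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  n <- fit$n; k <- fit$k
  if (n <= k + 1) stop_input("need n > k + 1 for studentized residuals")
  h <- fit$leverage
  if (any(h >= 1 - 1e-12))
    stop_input("perfect-leverage observation (h = 1) at index %d",
               which(h >= 1 - 1e-12)[1])
  e <- fit$residuals
  rss <- sum(e^2)
  if (fit$sigma <= .Machine$double.eps^0.5 * max(abs(fit$fitted), 1)) {
    ## exact fit: no observation is influential
    rstudent <- dffits <- rep(0, n)
    covratio <- rep(1, n)
  } else {
    s2_loo <- (rss - e^2 / (1 - h)) / (n - k - 1)
    rstudent <- e / sqrt(s2_loo * (1 - h))
    dffits <- rstudent * sqrt(h / (1 - h))
    ## det(s_i^2 (X_i'X_i)^{-1}) / det(s^2 (X'X)^{-1}) in closed form
    covratio <- (s2_loo / fit$sigma^2)^k / (1 - h)
  }

  dffits_cut <- dffits_cut %||% (2 * sqrt(k / n))
  covratio_cut <- covratio_cut %||% (3 * k / n)
  out <- data.frame(
    obs = seq_len(n), rstudent = rstudent, dffits = dffits,
    covratio = covratio,
    flag_rstudent = abs(rstudent) > rstudent_cut,
    flag_dffits = abs(dffits) > dffits_cut,
    flag_covratio = abs(covratio - 1) > covratio_cut)
  out$flagged <- out$flag_rstudent | out$flag_dffits | out$flag_covratio
  attr(out, "thresholds") <- c(rstudent = rstudent_cut, dffits = dffits_cut,
                               covratio = covratio_cut)
  class(out) <- c("influence_table", "data.frame")
  out
}

#' MM-estimation robust regression
#'
#' Two-stage robust least squares: stage 1 is an S-estimate of coefficients
#' and scale with a bisquare rho tuned for the requested breakdown point
#' (default 50%, c ~ 1.5476), initialized from seeded elemental subsamples
#' refined by concentration (iteratively reweighted least squares) steps;
#' stage 2 is an M-step with a bisquare psi tuned for the requested Gaussian
#' efficiency (default 95%, c ~ 4.685), holding the S-scale fixed.
#' Standard errors use the usual MM asymptotic covariance
#' \eqn{\hat\sigma^2 \frac{n}{n-k}\frac{\overline{\psi^2}}
#' {(\overline{\psi'})^2}(X'X)^{-1}} and z-statistics are referred to the
#' normal distribution.
#'
#' @param y Response vector.
#' @param X Design matrix (include the intercept column).
#' @param efficiency Gaussian efficiency of the M-stage (default 0.95).
#' @param breakdown Breakdown point of the S-stage (default 0.5).
#' @param nsamp Number of elemental subsamples (default 500).
#' @param seed RNG seed for subsampling (default 42; estimation is
#'   deterministic given the seed).
#' @param max_it,tol IRWLS iteration cap and relative-change tolerance.
#' @return Object of class `rls_fit`: `coefficients`, `scale`, `se`, `z`,
#'   `stars`, `weights` (final bisquare weights in [0, 1]), `converged`,
#'   `iterations`, `residuals`, plus the tuning constants used.
#' @export
fit_mm <- function(y, X, efficiency = 0.95, breakdown = 0.5,
                   nsamp = 500L, seed = 42L, max_it = 200L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop_input("y and X are misaligned")
  if (n <= 2 * k)
    stop_input("MM estimation needs n > 2k (n = %d, k = %d)", n, k)
  c1 <- bisquare_c_breakdown(breakdown)
  c2 <- bisquare_c_efficiency(efficiency)
  b <- breakdown

  ## ---- stage 1: S-estimate -------------------------------------------
  best <- with_seed(seed, {
    best <- list(s = Inf, beta = NULL)
    ols0 <- tryCatch(fit_ols(y, X), error = function(e) NULL)
    cand0 <- if (!is.null(ols0)) list(ols0$coefficients) else list()
    for (it in seq_len(nsamp)) {
      idx <- sample.int(n, k)
      beta <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                       error = function(e) NULL)
      if (is.null(beta) || !all(is.finite(beta))) next
      cand0[[length(cand0) + 1]] <- beta
    }
    for (beta in cand0) {
      r <- y - as.numeric(X %*% beta)
      s <- mscale(r, c1, b)
      if (s == 0) { best <- list(s = 0, beta = beta); break }
      ## two concentration steps before scoring
      for (cs in 1:2) {
        if (s == 0) break                  # exact-fit candidate
        w <- wt_bisq(r / s, c1)
        if (sum(w > 0) <= k) break
        beta_new <- tryCatch(
          qr.coef(qr(X * sqrt(w)), y * sqrt(w)),
          error = function(e) NULL)
        if (is.null(beta_new) || anyNA(beta_new)) break
        beta <- beta_new
        r <- y - as.numeric(X %*% beta)
        s <- mscale(r, c1, b)
      }
      if (s == 0) { best <- list(s = 0, beta = beta); break }
      if (s < best$s) best <- list(s = s, beta = beta)
    }
    best
  })
  if (is.null(best$beta)) stop_input("S-stage found no non-singular subsample")

  ## refine the best S-candidate to convergence
  beta <- best$beta
  s <- best$s
  if (s > 0) {
    for (it in seq_len(max_it)) {
      r <- y - as.numeric(X %*% beta)
      s <- mscale(r, c1, b)
      if (s == 0) break
      w <- wt_bisq(r / s, c1)
      if (sum(w > 0) <= k) break
      beta_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
      if (anyNA(beta_new)) break
      if (max(abs(beta_new - beta)) <=
          tol * max(1, max(abs(beta)))) { beta <- beta_new; break }
      beta <- beta_new
    }
  }
  s_final <- if (s > 0) mscale(y - as.numeric(X %*% beta), c1, b) else 0

  ## degenerate exact-fit case: scale 0, keep S coefficients
  if (s_final <= .Machine$double.eps^0.5 * max(abs(y), 1)) {
    r <- y - as.numeric(X %*% beta)
    return(rls_result(beta, X, r, s = max(s_final, 0), c2 = c2, c1 = c1,
                      efficiency = efficiency, breakdown = breakdown,
                      converged = TRUE, iterations = 0L))
  }

  ## ---- stage 2: M-step at fixed S-scale ------------------------------
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_it)) {
    r <- y - as.numeric(X %*% beta)
    w <- wt_bisq(r / s_final, c2)
    if (sum(w > 0) <= k) break
    beta_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    if (anyNA(beta_new)) break
    iterations <- it
    if (max(abs(beta_new - beta)) <= tol * max(1, max(abs(beta_new)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged)
    warning("MM estimation did not converge; returning last iterate",
            call. = FALSE)
  r <- y - as.numeric(X %*% beta)
  rls_result(beta, X, r, s = s_final, c2 = c2, c1 = c1,
             efficiency = efficiency, breakdown = breakdown,
             converged = converged, iterations = iterations)
}

rls_result <- function(beta, X, r, s, c2, c1, efficiency, breakdown,
                       converged, iterations) {
  n <- nrow(X); k <- ncol(X)
  if (s > 0) {
    u <- r / s
    a <- mean(psi_bisq(u, c2)^2)
    bb <- mean(dpsi_bisq(u, c2))
    XtX_inv <- chol2inv(qr.R(qr(X)))
    V <- s^2 * (n / (n - k)) * a / bb^2 * XtX_inv
    se <- sqrt(pmax(diag(V), 0))
    wts <- wt_bisq(u, c2)
  } else {
    se <- rep(0, k)
    V <- matrix(0, k, k)
    wts <- rep(1, n)
  }
  z <- ifelse(se > 0, beta / se, NA_real_)
  nm <- colnames(X) %||% paste0("x", seq_len(k))
  names(beta) <- names(se) <- names(z) <- nm
  structure(
    list(coefficients = beta, scale = s, se = se, z = z,
         stars = z_stars(z), weights = wts, vcov = V,
         residuals = r, n = n, k = k,
         converged = converged, iterations = iterations,
         tuning = c(c_breakdown = c1, c_efficiency = c2,
                    breakdown = breakdown, efficiency = efficiency)),
    class = "rls_fit"
  )
}

#' @export
print.rls_fit <- function(x, ...) {
  cat(sprintf("MM robust regression (scale = %.4g, %s)\n", x$scale,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(coef = x$coefficients, z = x$z, sig = x$stars)
  print(round2_df(tab, 4))
  invisible(x)
}

round2_df <- function(df, digits) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
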