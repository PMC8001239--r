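## Independent oracles used across test files.  These deliberately avoid the
## package's own code paths: loops instead of the vectorized identities the
## implementation relies on.

## Brute-force generalized FEVD: accumulate MA terms by the raw difference
## equation (impulse propagation), then form the variance shares entry by
## entry with explicit loops.
oracle_gfevd <- function(A_list, Sigma, H) {
  if (is.matrix(A_list)) A_list <- list(A_list)
  N <- nrow(Sigma); p <- length(A_list)
  ## impulse propagation: run the difference equation with a unit shock to
  ## series j at time 1; Psi[[h]][, j] is the response h - 1 steps later
  Psi <- lapply(seq_len(H), function(h) matrix(0, N, N))
  for (j in seq_len(N)) {
    y <- vector("list", H)
    for (h in seq_len(H)) {
      acc <- rep(0, N)
      if (h == 1) acc[j] <- 1
      for (l in seq_len(p))
        if (h - l >= 1) acc <- acc + as.numeric(A_list[[l]] %*% y[[h - l]])
      y[[h]] <- acc
      Psi[[h]][, j] <- acc
    }
  }
  theta <- matrix(0, N, N)
  den <- rep(0, N)
  for (i in seq_len(N)) {
    ei <- replace(rep(0, N), i, 1)
    for (h in seq_len(H)) {
      den[i] <- den[i] + as.numeric(t(ei) %*% Psi[[h]] %*% Sigma %*%
                                      t(Psi[[h]]) %*% ei)
    }
    for (j in seq_len(N)) {
      ej <- replace(rep(0, N), j, 1)
      num <- 0
      for (h in seq_len(H))
        num <- num + as.numeric(t(ei) %*% Psi[[h]] %*% Sigma %*% ej)^2
      theta[i, j] <- num / (Sigma[j, j] * den[i])
    }
  }
  theta / rowSums(theta)
}

## Literal leave-one-out influence statistics: refit n times.
oracle_influence <- function(y, X) {
  n <- nrow(X); k <- ncol(X)
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / (n - k)
  XtX_inv <- chol2inv(qr.R(qr(X)))
  rstudent <- dffits <- covratio <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fi <- lm.fit(Xi, yi)
    s2i <- sum(fi$residuals^2) / (n - 1 - k)
    pred_i <- as.numeric(X[i, ] %*% fi$coefficients)
    rstudent[i] <- (y[i] - pred_i) /
      sqrt(s2i * (1 + as.numeric(X[i, ] %*% chol2inv(qr.R(qr(Xi))) %*% X[i, ])))
    h_i <- as.numeric(X[i, ] %*% XtX_inv %*% X[i, ])
    dffits[i] <- (fit$fitted.values[i] - pred_i) / sqrt(s2i * h_i)
    covratio[i] <- det(s2i * chol2inv(qr.R(qr(Xi)))) / det(s2 * XtX_inv)
  }
  list(rstudent = rstudent, dffits = dffits, covratio = covratio)
}

## Dense HP trend: explicitly assembled (I + lambda K'K) system.
oracle_hp_trend <- function(y, lambda) {
  n <- length(y)
  K <- matrix(0, n - 2, n)
  for (r in seq_len(n - 2)) K[r, r:(r + 2)] <- c(1, -2, 1)
  solve(diag(n) + lambda * crossprod(K), y)
}

## Small default test world shared by several files.
test_world <- function(n_series = 4, weeks_end = "2003-12-31", seed = 7) {
  sim_config(n_series = n_series, seed = seed,
             calendar = make_calendar("2000-01-01", weeks_end))
}
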