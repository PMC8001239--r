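#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_numeric_vector <- function(x, name, min_len = 1L, allow_na = FALSE) {
  if (!is.numeric(x)) stop_input("`%s` must be numeric", name)
  if (length(x) < min_len)
    stop_input("`%s` must have length >= %d (got %d)", name, min_len, length(x))
  if (!allow_na && anyNA(x))
    stop_input("`%s` contains missing values (first at position %d)",
               name, which(is.na(x))[1])
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

symmetrize <- function(M) (M + t(M)) / 2

## Clip negative eigenvalues to zero; used as a guard after Kalman updates.
psd_floor <- function(M, warn_label = NULL) {
  M <- symmetrize(M)
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1)) {
    if (!is.null(warn_label))
      warning(sprintf("negative eigenvalue clipped in %s", warn_label),
              call. = FALSE)
    v <- pmax(ev$values, 0)
    M <- ev$vectors %*% (v * t(ev$vectors))
    M <- symmetrize(M)
  }
  M
}

spectral_radius <- function(M) {
  max(Mod(eigen(M, only.values = TRUE)$values))
}

## Significance stars from a two-sided normal p-value, Table-1 style.
z_stars <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}
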