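#' Default preprocessing recipe for the determinants regression
#'
#' Maps each monthly variable to a stationarity transform:
#' `"hp_cycle"` (Hodrick-Prescott cycle at `lambda`), `"difference"` (first
#' difference) or `"none"`.  Responses (the connectedness indices) and the
#' level covariates default to HP cycles; the Baumol cost variable enters as
#' its first difference ("growth"), scaled by `baumol_scale` (default 1e-2)
#' to mirror the conventional reporting scale.
#'
#' @param ... Named overrides, e.g. `leading_index = "difference"`.
#' @return Named list of transforms.
#' @export
default_recipe <- function(...) {
  recipe <- list(response = "hp_cycle",
                 young_dep = "hp_cycle", old_dep = "hp_cycle",
                 leading_index = "hp_cycle", medical_price = "hp_cycle",
                 primary_care_share = "hp_cycle", baumol = "difference")
  utils::modifyList(recipe, list(...))
}

## Build the regression design from a covariate table and a recipe.
## Returns design matrix (with intercept) + logical row-keep mask for
## alignment after differencing.
build_design <- function(covariates, recipe, lambda = 14400,
                         baumol_scale = 1e-2) {
  need <- c("young_dep", "old_dep", "leading_index", "medical_price",
            "primary_care_share", "baumol")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop_input("covariate table lacks column(s): %s",
               paste(miss, collapse = ", "))
  cols <- lapply(need, function(nm)
    apply_transform(covariates[[nm]], recipe[[nm]] %||% "hp_cycle", lambda))
  D <- do.call(cbind, cols)
  D[, need == "baumol"] <- D[, need == "baumol"] * baumol_scale
  colnames(D) <- c("young_dep", "old_dep", "leading_index", "medical_price",
                   "primary_care", "baumol_growth")
  D
}

#' Spillover determinants regression (Table-1-shaped grid)
#'
#' For the total connectedness index and each series' net total directional
#' index, runs OLS with influence diagnostics (to count RStudent / DFFITS /
#' CovRatio outliers) followed by MM-estimation robust least squares of the
#' index cycle on the demographic block (young/old dependency-ratio cycles),
#' the socioeconomic block (leading-index, medical-price cycles and Baumol
#' cost growth) and the healthcare-utilization block (primary-care share
#' cycle).
#'
#' @param indices Data frame of monthly indices: a `month` column plus `TCI`
#'   and one column per series' NTDCI (as produced by the pipeline's
#'   monthly aggregation).
#' @param covariates A [generate_covariates()]-shaped table aligned on the
#'   same months.
#' @param recipe Transform recipe, see [default_recipe()].
#' @param lambda HP smoothing parameter for monthly cycles (default 14400).
#' @param baumol_scale Scale applied to the Baumol growth regressor
#'   (default 1e-2).
#' @param efficiency,breakdown,nsamp,seed MM-estimation settings, see
#'   [fit_mm()].
#' @param rstudent_cut,dffits_cut,covratio_cut Influence-flag thresholds,
#'   see [influence_stats()].
#' @return Object of class `spillover_regression`: `table` (one row per
#'   response with coefficients, z-statistics, stars and per-criterion
#'   outlier counts), `fits` (named list of `rls_fit`), `ols_fits`,
#'   `influence`, `recipe`.
#' @export
spillover_regression <- function(indices, covariates,
                                 recipe = default_recipe(),
                                 lambda = 14400, baumol_scale = 1e-2,
                                 efficiency = 0.95, breakdown = 0.5,
                                 nsamp = 500L, seed = 42L,
                                 rstudent_cut = 2, dffits_cut = NULL,
                                 covratio_cut = NULL) {
  if (!("month" %in% names(indices)))
    stop_input("indices must have a `month` column")
  if (!("month" %in% names(covariates)))
    stop_input("covariates must have a `month` column")
  if (!identical(as.character(indices$month),
                 as.character(covariates$month))) {
    off <- union(setdiff(indices$month, covariates$month),
                 setdiff(covariates$month, indices$month))
    stop_input("monthly alignment failure; offending months: %s",
               paste(utils::head(off, 12), collapse = ", "))
  }

  D <- build_design(covariates, recipe, lambda, baumol_scale)
  resp_names <- setdiff(names(indices), "month")
  resp_tf <- recipe$response %||% "hp_cycle"

  rows <- list(); fits <- list(); olses <- list(); infl <- list()
  for (rn in resp_names) {
    yv <- apply_transform(indices[[rn]], resp_tf, lambda)
    keep <- stats::complete.cases(cbind(yv, D))
    Xk <- cbind(intercept = 1, D[keep, , drop = FALSE])
    yk <- yv[keep]
    ols <- fit_ols(yk, Xk)
    inf <- influence_stats(ols, rstudent_cut, dffits_cut, covratio_cut)
    mm <- fit_mm(yk, Xk, efficiency = efficiency, breakdown = breakdown,
                 nsamp = nsamp, seed = seed)
    rows[[rn]] <- data.frame(
      response = rn,
      as.list(stats::setNames(mm$coefficients,
                              paste0("coef_", names(mm$coefficients)))),
      as.list(stats::setNames(mm$z, paste0("z_", names(mm$z)))),
      as.list(stats::setNames(mm$stars, paste0("sig_", names(mm$z)))),
      n_rstudent = sum(inf$flag_rstudent),
      n_dffits = sum(inf$flag_dffits),
      n_covratio = sum(inf$flag_covratio),
      n_obs = mm$n,
      converged = mm$converged,
      stringsAsFactors = FALSE)
    fits[[rn]] <- mm
    olses[[rn]] <- ols
    infl[[rn]] <- inf
  }
  structure(
    list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
         fits = fits, ols_fits = olses, influence = infl,
         recipe = recipe,
         thresholds = attr(infl[[1]], "thresholds")),
    class = "spillover_regression"
  )
}

#' @export
print.spillover_regression <- function(x, ...) {
  cat("Robust least squares (MM) estimates of connectedness determinants\n")
  cat(format_regression_table(x), sep = "\n")
  invisible(x)
}

#' Format the regression grid as a fixed-width text table
#'
#' @param x A [spillover_regression()] result.
#' @return Character vector of table lines.
#' @export
format_regression_table <- function(x) {
  stopifnot(inherits(x, "spillover_regression"))
  tab <- x$table
  regs <- sub("^coef_", "", grep("^coef_", names(tab), value = TRUE))
  regs <- setdiff(regs, "intercept")
  hdr <- sprintf("%-8s %s %9s %8s %9s", "Index",
                 paste(sprintf("%22s", regs), collapse = " "),
                 "RStudent", "DFFITS", "CovRatio")
  lines <- hdr
  for (r in seq_len(nrow(tab))) {
    cells <- vapply(regs, function(g)
      sprintf("%9.3f (%6.2f)%-3s", tab[r, paste0("coef_", g)],
              tab[r, paste0("z_", g)], tab[r, paste0("sig_", g)]),
      character(1))
    lines <- c(lines, sprintf("%-8s %s %9d %8d %9d", tab$response[r],
                              paste(cells, collapse = " "),
                              tab$n_rstudent[r], tab$n_dffits[r],
                              tab$n_covratio[r]))
  }
  lines
}

#' Classify the demographic-transition effect on a spillover index
#'
#' Convex: significantly negative young-dependency and significantly
#' positive old-dependency coefficients (spillovers fall while the young
#' population dominates, then rise as the population ages); concave:
#' the reverse; positive-/negative-ageing: only the old-dependency
#' coefficient significant (by its sign); otherwise none.
#'
#' @param young_coef,old_coef Estimated cycle coefficients.
#' @param young_sig,old_sig Logical: coefficient significant at the chosen
#'   level?
#' @return One of `"convex"`, `"concave"`, `"positive-ageing"`,
#'   `"negative-ageing"`, `"none"`.
#' @export
classify_demographic_effect <- function(young_coef, young_sig,
                                        old_coef, old_sig) {
  if (young_sig && old_sig && young_coef < 0 && old_coef > 0) return("convex")
  if (young_sig && old_sig && young_coef > 0 && old_coef < 0) return("concave")
  if (!young_sig && old_sig)
    return(if (old_coef > 0) "positive-ageing" else "negative-ageing")
  "none"
}

#' Classify the business-cycle pattern of a spillover index
#'
#' @param leading_coef Leading-index cycle coefficient.
#' @param sig Logical: significant?
#' @return `"pro-cyclical"`, `"counter-cyclical"`, or `"acyclical"`.
#' @export
classify_cyclicality <- function(leading_coef, sig) {
  if (!sig) return("acyclical")
  if (leading_coef > 0) "pro-cyclical" else "counter-cyclical"
}
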