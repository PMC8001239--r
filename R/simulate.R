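#' Default simulation configuration for the synthetic expenditure world
#'
#' Describes the ground-truth data-generating process used in place of the
#' restricted claims data: `n_series` stationary weekly series from a VAR
#' with known coefficients and innovation covariance on the study calendar.
#' Defaults give a densely connected network — moderate own-lag persistence,
#' small uniform cross-lags, and equicorrelated innovations — so the
#' estimated total connectedness is high, as the application domain reports.
#'
#' @param n_series Number of series (default 18, labelled `CCS1..CCSn`).
#' @param var_order Lag order p of the true VAR (default 1).
#' @param coefficient_path Either one coefficient stack (list of p `N x N`
#'   matrices, or a single matrix for p = 1) used at every period, or a list
#'   of such stacks, one per weekly bin, for a time-varying truth (see
#'   [drift_path()]).  Default: own-lag 0.30, cross-lags 0.035 below the
#'   diagonal and 0.005 above it, so that low-index series are net
#'   transmitters and high-index series net receivers (the directional
#'   structure spillover studies report).
#' @param innovation_cov Symmetric positive-definite innovation covariance;
#'   default unit variances with equicorrelation 0.6.
#' @param intercept Intercept vector of the VAR (default 100, an
#'   expenditure-like level).
#' @param seed Integer RNG seed.
#' @param calendar A [make_calendar()] object; default the 2000-01-01 ..
#'   2015-09-30 window (822 weeks).
#' @param burn Burn-in periods discarded before the first retained week
#'   (default 200).
#' @param covariates Optional list of per-covariate settings overriding
#'   [generate_covariates()] defaults (see its documentation).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_series = 18L, var_order = 1L,
                       coefficient_path = NULL, innovation_cov = NULL,
                       intercept = 100, seed = 1L,
                       calendar = make_calendar("2000-01-01", "2015-09-30"),
                       burn = 200L, covariates = list()) {
  N <- as.integer(n_series)
  if (N < 2) stop_input("n_series must be >= 2")
  if (is.null(coefficient_path)) {
    A <- matrix(0.005, N, N)
    A[lower.tri(A)] <- 0.035
    diag(A) <- 0.30
    coefficient_path <- list(A)
    var_order <- 1L
  }
  if (is.null(innovation_cov)) {
    innovation_cov <- matrix(0.6, N, N); diag(innovation_cov) <- 1
  }
  cfg <- structure(
    list(n_series = N, var_order = as.integer(var_order),
         coefficient_path = coefficient_path,
         innovation_cov = as.matrix(innovation_cov),
         intercept = intercept, seed = as.integer(seed),
         calendar = calendar, burn = as.integer(burn),
         covariates = covariates),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  S <- cfg$innovation_cov
  if (max(abs(S - t(S))) > 1e-10)
    stop_input("innovation_cov must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_input("innovation_cov must be positive definite")
  for (info in iterate_stacks(cfg))
    if (!is_stationary(info$stack))
      stop_input(
        "non-stationary coefficient stack at period %s (companion radius %.4f)",
        info$label, spectral_radius(companion_matrix(info$stack)))
  invisible(cfg)
}

## Enumerate the distinct coefficient stacks of a config with period labels.
iterate_stacks <- function(cfg) {
  cp <- cfg$coefficient_path
  if (is.matrix(cp)) cp <- list(cp)
  if (is.matrix(cp[[1]]))
    return(list(list(stack = cp, label = "constant")))
  lapply(seq_along(cp), function(t) {
    s <- cp[[t]]
    if (is.matrix(s)) s <- list(s)
    list(stack = s, label = as.character(t))
  })
}

#' Smooth drift path between two coefficient stacks
#'
#' Builds a per-period coefficient path for a time-varying truth:
#' a deterministic half-cosine drift from `stack1` to `stack2`
#' (`type = "sine"`), or an abrupt switch at `n %/% 2` (`type = "step"`,
#' useful for tracking tests).
#'
#' @param stack1,stack2 Coefficient stacks (matrix or list of matrices).
#' @param n Number of periods.
#' @param type `"sine"` or `"step"`.
#' @return A list of `n` stacks suitable as `coefficient_path`.
#' @export
drift_path <- function(stack1, stack2, n, type = c("sine", "step")) {
  type <- match.arg(type)
  if (is.matrix(stack1)) stack1 <- list(stack1)
  if (is.matrix(stack2)) stack2 <- list(stack2)
  w <- switch(type,
              sine = 0.5 * (1 - cos(pi * (seq_len(n) - 1) / (n - 1))),
              step = as.numeric(seq_len(n) > n %/% 2))
  lapply(w, function(wt)
    lapply(seq_along(stack1), function(l)
      (1 - wt) * stack1[[l]] + wt * stack2[[l]]))
}

#' Simulate a weekly expenditure panel with known spillover structure
#'
#' Runs the VAR recursion of `config` with Gaussian innovations, discards the
#' burn-in, and returns one row per weekly calendar bin.  Bit-reproducible
#' given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `expenditure_panel`: list with `calendar`,
#'   `values` (weeks x n_series matrix, columns `CCS1..`), `config_seed`.
#' @export
generate_expenditure_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$calendar$n_weeks
  vals <- with_seed(config$seed,
                    simulate_var_path(config$coefficient_path,
                                      config$innovation_cov, n,
                                      intercept = config$intercept,
                                      burn = config$burn))
  colnames(vals) <- paste0("CCS", seq_len(config$n_series))
  structure(list(calendar = config$calendar, values = vals,
                 series_ids = colnames(vals), config_seed = config$seed),
            class = "expenditure_panel")
}

#' @export
print.expenditure_panel <- function(x, ...) {
  cat(sprintf("<expenditure_panel> %d weeks x %d series (%s .. %s)\n",
              nrow(x$values), ncol(x$values),
              format(x$calendar$start), format(x$calendar$end)))
  invisible(x)
}

## Deterministic trend + AR(1) cycle building block for covariates.
trend_cycle_series <- function(n, from, to, phi, sd_cycle) {
  trend <- seq(from, to, length.out = n)
  if (sd_cycle <= 0) return(trend)
  e <- stats::rnorm(n, sd = sd_cycle)
  cyc <- as.numeric(stats::filter(e, phi, method = "recursive"))
  trend + cyc
}

#' Simulate monthly covariates for the spillover regression
#'
#' Produces the monthly regressors of the determinants equation: young- and
#' old-age economic dependency ratios (population <= 15 / labor force and
#' population 65+ / labor force), a composite leading index, a medical price
#' index (base 2014 = 100 scale), the primary-care share of outpatient
#' visits, and a Baumol cost variable assembled as
#' `(wage growth - productivity growth) / healthcare labor share`.
#' Each covariate is a deterministic smooth trend plus an AR(1) cycle; by
#' default the young ratio trends down and the old ratio up (demographic
#' transition).  Per-covariate settings (`from`, `to`, `phi`, `sd`) can be
#' overridden through `config$covariates`, e.g.
#' `sim_config(covariates = list(old_dep = list(sd = 0)))`.
#'
#' @param config A [sim_config()] object (supplies seed and overrides).
#' @param calendar A [make_calendar()] object; defaults to the config's.
#' @return Object of class `covariate_table`: data frame with one row per
#'   month and columns `month`, `young_dep`, `old_dep`, `leading_index`,
#'   `medical_price`, `primary_care_share`, `wage_growth`,
#'   `productivity_growth`, `labor_share`, `baumol`.
#' @export
generate_covariates <- function(config, calendar = config$calendar) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(calendar, "spill_calendar"))
    stop_input("`calendar` must be a spill_calendar")
  M <- calendar$n_months
  if (M < 1) stop_input("calendar has no months")

  defaults <- list(
    young_dep           = list(from = 0.55,  to = 0.33,  phi = 0.85, sd = 0.004),
    old_dep             = list(from = 0.14,  to = 0.33,  phi = 0.85, sd = 0.004),
    leading_index       = list(from = 95,    to = 115,   phi = 0.95, sd = 0.8),
    medical_price       = list(from = 82,    to = 101,   phi = 0.80, sd = 0.4),
    primary_care_share  = list(from = 0.70,  to = 0.66,  phi = 0.80, sd = 0.006),
    wage_growth         = list(from = 0.004, to = 0.002, phi = 0.50, sd = 0.002),
    productivity_growth = list(from = 0.005, to = 0.002, phi = 0.50, sd = 0.002),
    labor_share         = list(from = 0.030, to = 0.055, phi = 0.70, sd = 0.0008)
  )
  for (nm in names(config$covariates)) {
    if (!nm %in% names(defaults))
      stop_input("unknown covariate override '%s'", nm)
    defaults[[nm]] <- utils::modifyList(defaults[[nm]],
                                        config$covariates[[nm]])
  }

  cols <- with_seed(config$seed + 1L, {
    lapply(defaults, function(d)
      trend_cycle_series(M, d$from, d$to, d$phi, d$sd))
  })

  if (any(cols$labor_share <= 0))
    stop_input("labor share <= 0 at month %s",
               calendar$months$label[which(cols$labor_share <= 0)[1]])
  cols$primary_care_share <- pmin(pmax(cols$primary_care_share, 0), 1)
  baumol <- (cols$wage_growth - cols$productivity_growth) / cols$labor_share

  out <- data.frame(month = calendar$months$label,
                    young_dep = cols$young_dep,
                    old_dep = cols$old_dep,
                    leading_index = cols$leading_index,
                    medical_price = cols$medical_price,
                    primary_care_share = cols$primary_care_share,
                    wage_growth = cols$wage_growth,
                    productivity_growth = cols$productivity_growth,
                    labor_share = cols$labor_share,
                    baumol = baumol,
                    stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Ground-truth connectedness of a known VAR
#'
#' Computes the connectedness index family from true parameters through the
#' same generalized-FEVD code path used in estimation; the recovery oracle
#' for simulation studies.
#'
#' @param coefficient_stack Coefficient stack (matrix or list of matrices).
#' @param innovation_cov Innovation covariance.
#' @param horizon Forecast horizon H (default 10).
#' @return A `connectedness_table` (see [connectedness_indices()]).
#' @export
true_connectedness <- function(coefficient_stack, innovation_cov,
                               horizon = 10L) {
  if (is.matrix(coefficient_stack)) coefficient_stack <- list(coefficient_stack)
  if (!is_stationary(coefficient_stack))
    stop_input("coefficient stack is non-stationary (companion radius %.4f)",
               spectral_radius(companion_matrix(coefficient_stack)))
  params <- var_params(coefficient_stack, innovation_cov)
  connectedness_indices(gfevd(params, horizon))
}

#' Write / read a panel as CSV with an ISO-8601 date column
#' @param panel An `expenditure_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "expenditure_panel"))
  df <- data.frame(date = format(panel$calendar$week_starts),
                   signif(panel$values, 10), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param end_date End date of the study window (the CSV stores only week
#'   start dates); defaults to the last week start, which reproduces the
#'   original bin count and month enumeration exactly.
#' @export
read_panel_csv <- function(path, end_date = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  dates <- as.Date(df[[1]])
  if (anyNA(dates)) stop_input("first column of %s must be ISO dates", path)
  end <- if (is.null(end_date)) dates[length(dates)] else as.Date(end_date)
  cal <- make_calendar(dates[1], end)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) != cal$n_weeks)
    stop_input("panel rows (%d) do not match calendar bins (%d)",
               nrow(vals), cal$n_weeks)
  structure(list(calendar = cal, values = vals,
                 series_ids = colnames(vals), config_seed = NA_integer_),
            class = "expenditure_panel")
}
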