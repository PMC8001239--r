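#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis.  Can be built in code or
#' loaded from a YAML file with [load_config()].
#'
#' @param input_mode `"synthetic"` (default: simulate panel and covariates)
#'   or `"csv"` (load from `panel_csv` / `covariates_csv`).
#' @param panel_csv,covariates_csv Input paths for csv mode.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in every output's metadata.
#' @param sim List of [sim_config()] arguments for synthetic mode.
#' @param p VAR order; `NULL` selects by BIC over 1..4.
#' @param kappa1,kappa2 TVP-VAR forgetting factors.
#' @param prior_fraction Training fraction for the TVP prior.
#' @param horizon GFEVD forecast horizon H.
#' @param min_edge Minimum edge weight for the network export.
#' @param recipe Preprocessing recipe, see [default_recipe()].
#' @param lambda HP smoothing parameter for monthly cycles.
#' @param mm List of MM settings (`efficiency`, `breakdown`, `nsamp`).
#' @param thresholds List of influence thresholds (`rstudent`, `dffits`,
#'   `covratio`; `NULL` entries use the defaults).
#' @param log_level `"info"` (default), `"quiet"`, or `"debug"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "csv"),
                            panel_csv = NULL, covariates_csv = NULL,
                            out_dir = "spillnet-output", seed = 1L,
                            sim = list(), p = 1L, kappa1 = 0.99,
                            kappa2 = 0.96, prior_fraction = 0.1,
                            horizon = 10L, min_edge = 0,
                            recipe = default_recipe(), lambda = 14400,
                            mm = list(efficiency = 0.95, breakdown = 0.5,
                                      nsamp = 500L),
                            thresholds = list(rstudent = 2, dffits = NULL,
                                              covratio = NULL),
                            log_level = "info") {
  input_mode <- match.arg(input_mode)
  if (input_mode == "csv") {
    for (pth in c(panel_csv, covariates_csv))
      if (is.null(pth) || !file.exists(pth))
        stop_input("csv mode requires existing panel_csv and covariates_csv (missing: %s)",
                   pth %||% "NULL")
  }
  structure(
    list(input_mode = input_mode, panel_csv = panel_csv,
         covariates_csv = covariates_csv, out_dir = out_dir,
         seed = as.integer(seed), sim = sim, p = p,
         kappa1 = kappa1, kappa2 = kappa2,
         prior_fraction = prior_fraction, horizon = as.integer(horizon),
         min_edge = min_edge, recipe = recipe, lambda = lambda,
         mm = mm, thresholds = thresholds, log_level = log_level),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read (e.g. `seed`).
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  raw <- yaml::read_yaml(path) %||% list()
  dots <- list(...)
  raw[names(dots)] <- dots
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop_input("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

plog <- function(config, level, ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[config$log_level %||% "info"]] >= ranks[[level]])
    message(sprintf(...))
}

write_table10 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 10)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full spillover analysis pipeline
#'
#' Simulate (or load) the weekly panel -> unit-root screening -> TVP-VAR ->
#' dynamic and static connectedness -> network export and node roles ->
#' monthly aggregation -> covariate cycles -> robust determinants
#' regression.  All outputs are written as CSV/DOT/JSON under
#' `config$out_dir`; a manifest records the seed, a config hash, the package
#' version and an md5 checksum for every file.  Identical config and seed
#' give byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`panel`,
#'   `covariates`, `pp_report`, `states`, `dynamic`, `static_table`,
#'   `network`, `roles`, `monthly_indices`, `regression`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)))
  }

  ## 1. inputs
  if (config$input_mode == "synthetic") {
    plog(config, "info", "simulating panel and covariates (seed %d)",
         config$seed)
    scfg <- stage("simulate", do.call(
      sim_config, utils::modifyList(list(seed = config$seed), config$sim)))
    panel <- stage("simulate", generate_expenditure_panel(scfg))
    covariates <- stage("simulate", generate_covariates(scfg))
    files <- c(files, write_panel_csv(panel, file.path(config$out_dir,
                                                       "panel.csv")))
    files <- c(files, write_table10(as.data.frame(covariates),
                                    file.path(config$out_dir,
                                              "covariates.csv")))
  } else {
    plog(config, "info", "loading panel from %s", config$panel_csv)
    panel <- stage("load", read_panel_csv(config$panel_csv))
    covariates <- stage("load", utils::read.csv(config$covariates_csv,
                                                check.names = FALSE))
  }
  cal <- panel$calendar

  ## 2. unit-root screening
  pp_report <- stage("pp_screen", {
    do.call(rbind, lapply(colnames(panel$values), function(id) {
      r <- pp_test(panel$values[, id])
      data.frame(series = id, z_tau = r$z_tau, z_rho = r$z_rho,
                 bandwidth = r$bandwidth, spec = r$deterministic_spec,
                 crit_5pct = r$crit_5pct, reject_5pct = r$reject_5pct)
    }))
  })
  files <- c(files, write_table10(pp_report,
                                  file.path(config$out_dir, "pp_report.csv")))
  plog(config, "info", "PP screening: %d/%d series reject the unit root",
       sum(pp_report$reject_5pct), nrow(pp_report))

  ## 3. TVP-VAR
  p <- config$p %||% select_var_order(panel)
  plog(config, "info", "fitting TVP-VAR (p = %d, kappa1 = %.3f, kappa2 = %.3f)",
       p, config$kappa1, config$kappa2)
  states <- stage("tvp_var", fit_tvp_var(panel, p = p,
                                         kappa1 = config$kappa1,
                                         kappa2 = config$kappa2,
                                         prior_fraction = config$prior_fraction))

  ## 4. connectedness
  plog(config, "info", "computing dynamic connectedness (H = %d)",
       config$horizon)
  dynamic <- stage("connectedness", dynamic_connectedness(states,
                                                          config$horizon))
  dyn_df <- data.frame(date = format(dynamic$dates), tci = dynamic$tci,
                       dynamic$ntdci, check.names = FALSE)
  names(dyn_df)[-(1:2)] <- paste0("ntdci_", dynamic$series_ids)
  files <- c(files, write_table10(dyn_df, file.path(config$out_dir,
                                                    "dynamic_indices.csv")))

  static_table <- stage("static", average_table(dynamic))
  stat_long <- data.frame(
    from_series = rep(rownames(static_table$fevd),
                      each = ncol(static_table$fevd)),
    to_series = rep(colnames(static_table$fevd),
                    nrow(static_table$fevd)),
    share = as.numeric(t(static_table$fevd)),
    npdci = as.numeric(t(static_table$npdci)))
  files <- c(files, write_table10(stat_long,
                                  file.path(config$out_dir,
                                            "static_table.csv")))
  network <- stage("network", export_network(static_table, config$min_edge))
  write_network(network, file.path(config$out_dir, "edges.csv"),
                file.path(config$out_dir, "network.dot"))
  files <- c(files, file.path(config$out_dir, c("edges.csv", "network.dot")))
  roles <- stage("roles", classify_nodes(dynamic))
  files <- c(files, write_table10(roles, file.path(config$out_dir,
                                                   "node_roles.csv")))
  plog(config, "info", "static TCI = %.2f%%; %d pure transmitters",
       static_table$tci, sum(roles$purity == "pure transmitter"))

  ## 5. monthly aggregation (weekly indices first, then monthly averages)
  monthly <- stage("aggregate", {
    idx <- cbind(TCI = dynamic$tci, dynamic$ntdci)
    ## indices start at week p + 1: average within months over covered weeks
    sub_cal <- cal
    sub_cal$week_month <- cal$week_month[(p + 1):cal$n_weeks]
    sub_cal$n_weeks <- cal$n_weeks - p
    agg <- aggregate_weekly_to_monthly(idx, sub_cal)
    data.frame(month = rownames(agg), agg, check.names = FALSE,
               row.names = NULL)
  })
  files <- c(files, write_table10(monthly, file.path(config$out_dir,
                                                     "monthly_indices.csv")))

  ## 6. covariate cycles (for reference output)
  cyc <- stage("cycles", {
    D <- build_design(covariates, config$recipe, config$lambda)
    data.frame(month = covariates$month, D, check.names = FALSE)
  })
  files <- c(files, write_table10(cyc, file.path(config$out_dir,
                                                 "covariate_cycles.csv")))

  ## 7. robust determinants regression
  plog(config, "info", "running determinants regression (%d responses)",
       ncol(monthly) - 1)
  regression <- stage("regression", spillover_regression(
    monthly, covariates, recipe = config$recipe, lambda = config$lambda,
    efficiency = config$mm$efficiency %||% 0.95,
    breakdown = config$mm$breakdown %||% 0.5,
    nsamp = config$mm$nsamp %||% 500L,
    seed = config$seed,
    rstudent_cut = config$thresholds$rstudent %||% 2,
    dffits_cut = config$thresholds$dffits,
    covratio_cut = config$thresholds$covratio))
  files <- c(files, write_table10(regression$table,
                                  file.path(config$out_dir,
                                            "regression_table.csv")))
  writeLines(format_regression_table(regression),
             file.path(config$out_dir, "regression_table.txt"))
  files <- c(files, file.path(config$out_dir, "regression_table.txt"))

  ## 8. manifest
  cfg_yaml <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), cfg_yaml)
  files <- c(files, cfg_yaml)
  manifest <- list(
    package = "spillnet",
    version = as.character(utils::packageVersion("spillnet")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    var_order = p,
    horizon = config$horizon,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  plog(config, "info", "wrote %d artifacts to %s", length(files) + 1,
       config$out_dir)

  invisible(list(panel = panel, covariates = covariates,
                 pp_report = pp_report, states = states, dynamic = dynamic,
                 static_table = static_table, network = network,
                 roles = roles, monthly_indices = monthly,
                 regression = regression, manifest = manifest,
                 config = config))
}

## Serializable view of a config (drops function/complex entries cleanly).
config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- lapply(out$sim, function(v)
    if (is.matrix(v)) as.list(as.data.frame(v)) else v)
  out
}
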