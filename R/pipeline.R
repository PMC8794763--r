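#' Run the full benchmarking pipeline
#'
#' Expanding-window one-step-ahead forecasts for every registered model,
#' Bayesian weight updating over the AHM candidate set, a weighted
#' model-averaged AHM forecast series (using the weights available at the
#' START of each year, i.e. the posterior through the previous year), and
#' a skill report benchmarked against a designated null model.
#'
#' @param data list with `abundance`, `wetland` and (for AHM models)
#'   `harvest` series, or an `ahm_scenario` bundle.
#' @param models character vector of model ids to run.
#' @param eval_years length-2 target-year window `c(first, last)`.
#' @param null_id benchmark null for the skill report.
#' @param weight_models models included in weight updating (default: the
#'   registered AHM models); a model-averaged series `"AHMavg"` is added
#'   when two or more are present.
#' @param ahm_params,prior,standardization,use_obs_error passed to
#'   [run_one_step_ahead()].
#' @return A list of class `ahm_run`: `forecasts` (forecast table
#'   including any `AHMavg` rows), `skill` ([skill_report()] output),
#'   `weights` ([weight_trajectory()] output or `NULL`).
#' @export
run_pipeline <- function(data, models = c(ahm_model_ids(), "persistence",
                                          "wetland"),
                         eval_years, null_id = "persistence",
                         weight_models = intersect(models, ahm_model_ids()),
                         ahm_params = default_ahm_params(),
                         prior = wetland_prior(),
                         standardization = "recursive",
                         use_obs_error = TRUE) {
  if (inherits(data, "ahm_scenario")) {
    data <- list(abundance = data$abundance, wetland = data$wetland,
                 harvest = data$harvest)
  }
  table <- run_one_step_ahead(data, models, eval_years,
                              ahm_params = ahm_params, prior = prior,
                              standardization = standardization,
                              use_obs_error = use_obs_error)
  weights <- NULL
  if (length(weight_models) >= 1) {
    init <- init_weights(weight_models)
    weights <- weight_trajectory(table, init)
    if (length(weight_models) >= 2) {
      avg <- average_series(table, weights, weight_models)
      table <- structure(rbind(table, avg),
                         class = c("forecast_table", "data.frame"))
    }
  }
  skill <- skill_report(table, null_id = null_id)
  structure(list(forecasts = table, skill = skill, weights = weights),
            class = "ahm_run")
}

# Model-averaged forecast rows using start-of-year weights.
average_series <- function(table, weights, weight_models) {
  init <- attr(weights, "init")
  years <- sort(unique(table$target_year))
  rows <- list()
  for (y in years) {
    recs <- table[table$target_year == y &
                    table$model_id %in% weight_models, , drop = FALSE]
    if (nrow(recs) != length(weight_models)) next
    prev <- weights[weights$year < y, , drop = FALSE]
    w <- if (nrow(prev)) {
      unlist(prev[nrow(prev), weight_models])
    } else {
      init
    }
    avg <- model_average(recs[, setdiff(names(recs), "observed")],
                         w, model_id = "AHMavg")
    avg$observed <- recs$observed[1]
    rows[[length(rows) + 1L]] <- avg
  }
  do.call(rbind, rows)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "ahmnull_out",
    models = c(ahm_model_ids(), "persistence", "wetland"),
    weight_models = ahm_model_ids(),
    null_id = "persistence",
    standardization = "recursive",
    use_obs_error = TRUE,
    eval_years = NULL,
    data = list(abundance = NULL, wetland = NULL, harvest = NULL),
    simulate = list(generator = "SaRw", n_years = 40, N0 = 8,
                    start_year = 1980, beta = 0.1, process_sd = 0.05),
    ahm = default_ahm_params(),
    null_models = list(beta_mean = 0, beta_scale = 100,
                       a = 0.01, b = 0.01)
  )
}

merge_config <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Any subset of the defaults may be overridden; unknown keys are kept
#' (and ignored by the pipeline). See `pipeline_defaults()` in the source
#' for the full schema: `seed`, `outdir`, `models`, `weight_models`,
#' `null_id`, `standardization`, `eval_years`, `data:` input CSV paths,
#' `simulate:` scenario settings, `ahm:` submodel parameters,
#' `null_models:` prior hyperparameters.
#'
#' @param path YAML file path.
#' @return A named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(pipeline_defaults(), if (is.null(user)) list() else
    user)
  if (!is.null(cfg$ahm$survival$s0)) {
    cfg$ahm$survival$s0 <- unlist(cfg$ahm$survival$s0)
  }
  cfg
}

config_scenario <- function(cfg) {
  sim <- cfg$simulate
  args <- list(seed = cfg$seed, ahm = cfg$ahm)
  for (nm in intersect(names(sim), names(formals(scenario_spec)))) {
    args[[nm]] <- if (nm == "harvest" && !is.null(sim$harvest$mean)) {
      h <- sim$harvest; h$mean <- unlist(h$mean); h
    } else {
      sim[[nm]]
    }
  }
  do.call(scenario_spec, args)
}

#' Simulate a scenario from a config file
#'
#' Thin wrapper over [simulate_population()] and [write_scenario()]:
#' validates the configuration, simulates the bundle, and writes
#' `abundance.csv`, `wetland.csv`, `harvest.csv` and `truth.json`.
#'
#' @param config path to a YAML config, or a config list from
#'   [read_run_config()].
#' @param outdir output directory (overrides the config).
#' @param seed seed (overrides the config).
#' @return Named vector of output paths, invisibly.
#' @export
cmd_simulate <- function(config, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  bundle <- simulate_population(config_scenario(cfg))
  write_scenario(bundle, cfg$outdir)
}

load_run_data <- function(cfg) {
  paths <- cfg$data
  if (is.null(paths$abundance)) {
    # no input files: fall back to the simulated bundle in outdir
    paths <- list(abundance = file.path(cfg$outdir, "abundance.csv"),
                  wetland = file.path(cfg$outdir, "wetland.csv"),
                  harvest = file.path(cfg$outdir, "harvest.csv"))
  }
  data <- list(abundance = read_series(paths$abundance, "abundance"),
               wetland = read_series(paths$wetland, "wetland"))
  if (!is.null(paths$harvest) && file.exists(paths$harvest)) {
    data$harvest <- read_series(paths$harvest, "harvest")
  }
  data
}

#' Run the pipeline from a config file and write all outputs
#'
#' Executes forecasting, scoring and weight updating, writing
#' `forecasts.csv`, `skill.json`, `weights.csv`, `manifest.json` and
#' (optionally) `forecast_vs_observed.png` to the output directory.
#'
#' @param config path to a YAML config, or a config list.
#' @param outdir,seed optional overrides.
#' @param plot write the forecast-vs-observed scatter (default `TRUE`).
#' @return The `ahm_run` result list, invisibly; output paths in
#'   `attr(, "paths")`.
#' @export
cmd_run <- function(config, outdir = NULL, seed = NULL, plot = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  data <- load_run_data(cfg)
  eval_years <- cfg$eval_years
  if (is.null(eval_years)) {
    yrs <- data$abundance$year
    eval_years <- c(yrs[min(11L, length(yrs) - 1L)], yrs[length(yrs)])
  }
  prior <- wetland_prior(beta_mean = cfg$null_models$beta_mean,
                         beta_scale = cfg$null_models$beta_scale,
                         a = cfg$null_models$a, b = cfg$null_models$b)
  res <- run_pipeline(data, models = cfg$models,
                      eval_years = as.integer(eval_years),
                      null_id = cfg$null_id,
                      weight_models = cfg$weight_models,
                      ahm_params = cfg$ahm, prior = prior,
                      standardization = cfg$standardization,
                      use_obs_error = cfg$use_obs_error)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(forecasts = file.path(cfg$outdir, "forecasts.csv"),
             skill = file.path(cfg$outdir, "skill.json"),
             weights = file.path(cfg$outdir, "weights.csv"),
             manifest = file.path(cfg$outdir, "manifest.json"))
  fdf <- as.data.frame(res$forecasts)
  utils::write.csv(fdf[, c("model_id", "target_year", "mean", "sd",
                           "family", "observed")],
                   paths[["forecasts"]], row.names = FALSE)
  skill_out <- list(scores = as.data.frame(res$skill),
                    null_id = attr(res$skill, "null_id"),
                    score_definition = "nrmse=rmse/mean(obs); nmsd=mean(pred-obs)/mean(obs); v1")
  jsonlite::write_json(skill_out, paths[["skill"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(res$weights)) {
    utils::write.csv(as.data.frame(res$weights), paths[["weights"]],
                     row.names = FALSE)
  }
  if (isTRUE(plot)) {
    paths <- c(paths,
               plot = file.path(cfg$outdir, "forecast_vs_observed.png"))
    plot_forecasts(res, paths[["plot"]])
  }
  inputs <- cfg$data
  if (is.null(inputs$abundance)) {
    inputs <- list(abundance = file.path(cfg$outdir, "abundance.csv"),
                   wetland = file.path(cfg$outdir, "wetland.csv"),
                   harvest = file.path(cfg$outdir, "harvest.csv"))
  }
  manifest <- list(
    package = "ahmnull",
    version = as.character(utils::packageVersion("ahmnull")),
    seed = cfg$seed,
    config = cfg,
    input_checksums = as.list(tools::md5sum(unlist(inputs[
      vapply(inputs, function(p) !is.null(p) && file.exists(p),
             logical(1))]))),
    outputs = unname(paths))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(res, "paths") <- paths
  invisible(res)
}

#' Score an existing forecast table from CSV
#'
#' @param forecasts_csv path to a `forecasts.csv` written by [cmd_run()].
#' @param null_id benchmark null model id.
#' @param out optional path for `skill.json`.
#' @return The [skill_report()] data frame, invisibly when `out` is set.
#' @export
cmd_score <- function(forecasts_csv, null_id = "persistence", out = NULL) {
  tab <- utils::read.csv(forecasts_csv, stringsAsFactors = FALSE)
  tab <- structure(tab, class = c("forecast_table", "data.frame"))
  sk <- skill_report(tab, null_id = null_id)
  if (!is.null(out)) {
    jsonlite::write_json(list(scores = as.data.frame(sk),
                              null_id = null_id),
                         out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sk))
  }
  sk
}

#' Compute a weight trajectory from a forecast CSV
#'
#' Re-evaluating predictive densities requires the family parameters, so
#' this reads the full-precision table written by [cmd_run()] only when
#' the parameter columns are present; otherwise forecasts are treated as
#' normal with the stored mean/sd.
#'
#' @param forecasts_csv path to a forecasts CSV.
#' @param model_ids models to weight (default: AHM models found).
#' @param out optional path for `weights.csv`.
#' @return A `weight_series` data frame.
#' @export
cmd_weights <- function(forecasts_csv, model_ids = NULL, out = NULL) {
  tab <- utils::read.csv(forecasts_csv, stringsAsFactors = FALSE)
  if (!all(c("par1", "par2", "par3") %in% names(tab))) {
    tab$par1 <- tab$mean
    tab$par2 <- tab$sd
    tab$par3 <- NA_real_
    tab$family <- "normal"
  }
  tab <- structure(tab, class = c("forecast_table", "data.frame"))
  if (is.null(model_ids)) {
    model_ids <- intersect(ahm_model_ids(), unique(tab$model_id))
  }
  w <- weight_trajectory(tab, init_weights(model_ids))
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(w), out, row.names = FALSE)
  }
  w
}

#' Forecast-vs-observed scatter with skill annotations
#'
#' One panel per model: predicted mean against the eventual observation,
#' with the 1:1 bullseye line dashed and the panel's NRMSE and NMSD
#' printed in the corner. Points darken with year.
#'
#' @param run an `ahm_run` from [run_pipeline()] or [cmd_run()].
#' @param path optional file path; when given the plot is saved there.
#' @return The ggplot object, invisibly when saved.
#' @export
plot_forecasts <- function(run, path = NULL) {
  tab <- as.data.frame(run$forecasts)
  tab <- tab[!is.na(tab$observed), , drop = FALSE]
  sk <- as.data.frame(run$skill)
  sk$label <- sprintf("NRMSE %.3f\nNMSD %+.3f", sk$nrmse, sk$nmsd)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$observed,
                                         y = .data$mean,
                                         colour = .data$target_year)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#a1d99b", high = "#00441b",
                                   name = "year") +
    ggplot2::facet_wrap(~model_id) +
    ggplot2::geom_text(data = sk,
                       ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.05, vjust = 1.1,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = "observed abundance (millions)",
                  y = "forecast mean (millions)") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}
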