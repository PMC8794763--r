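#' Construct a one-step-ahead forecast record
#'
#' A forecast record is one model's predictive distribution for one target
#' year, stored as a one-row data frame carrying both moment summaries on
#' the abundance scale (`mean`, `sd`, millions of birds) and the exact
#' distribution family with its parameters, so that downstream weight
#' updating can evaluate the true predictive density at the eventual
#' observation.
#'
#' Families and their parameter slots:
#' * `"normal"` — `par1` mean, `par2` sd (abundance scale);
#' * `"lognormal"` — `par1` meanlog, `par2` sdlog;
#' * `"student-t"` — location `par1`, scale `par2`, df `par3` of a Student-t
#'   on log abundance (the `mean`/`sd` columns use a moment-matched normal
#'   approximation of the log-scale t, since the exact lognormal-t moments
#'   do not exist);
#' * `"mixture"` — moment summaries only (used for model-averaged records).
#'
#' @param model_id model identifier string.
#' @param target_year calendar year being forecast.
#' @param family one of `"normal"`, `"lognormal"`, `"student-t"`,
#'   `"mixture"`.
#' @param par1,par2,par3 family parameters (see above).
#' @param mean,sd abundance-scale moments; computed from the family
#'   parameters when not supplied.
#' @return A one-row data frame of class `forecast_record`.
#' @export
forecast_record <- function(model_id, target_year, family,
                            par1 = NA_real_, par2 = NA_real_,
                            par3 = NA_real_, mean = NULL, sd = NULL) {
  family <- match.arg(family, c("normal", "lognormal", "student-t",
                                "mixture"))
  if (is.null(mean) || is.null(sd)) {
    mom <- switch(family,
      normal = c(par1, par2),
      lognormal = {
        mu <- exp(par1 + par2^2 / 2)
        c(mu, mu * sqrt(exp(par2^2) - 1))
      },
      "student-t" = {
        # normal approximation on the log scale, variance-matched to the t
        s_eff <- if (par3 > 2) par2 * sqrt(par3 / (par3 - 2)) else par2
        mu <- exp(par1 + s_eff^2 / 2)
        c(mu, mu * sqrt(exp(s_eff^2) - 1))
      },
      mixture = stop("mixture records need explicit mean/sd", call. = FALSE)
    )
    mean <- mom[1]; sd <- mom[2]
  }
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd < 0) {
    stop("forecast record needs mean > 0 and sd >= 0", call. = FALSE)
  }
  structure(
    data.frame(model_id = model_id, target_year = as.integer(target_year),
               mean = mean, sd = sd, family = family,
               par1 = par1, par2 = par2, par3 = par3,
               stringsAsFactors = FALSE),
    class = c("forecast_record", "data.frame"))
}

#' Log predictive density of a forecast record at an observation
#'
#' @param rec a `forecast_record` row (or a data frame row with the same
#'   columns).
#' @param x observed abundance (millions), > 0.
#' @return Log density. Degenerate records (`sd == 0`) return `Inf` when
#'   the observation matches the point mass to within 1e-9 and `-Inf`
#'   otherwise; [update_weights()] handles this case explicitly.
#' @export
forecast_log_density <- function(rec, x) {
  stopifnot(x > 0)
  if (rec$sd == 0) {
    return(if (abs(x - rec$mean) < 1e-9) Inf else -Inf)
  }
  switch(as.character(rec$family),
    normal = stats::dnorm(x, rec$par1, rec$par2, log = TRUE),
    lognormal = stats::dlnorm(x, rec$par1, rec$par2, log = TRUE),
    "student-t" = stats::dt((log(x) - rec$par1) / rec$par2, df = rec$par3,
                            log = TRUE) - log(rec$par2) - log(x),
    stop("no evaluable density for family ", rec$family, call. = FALSE)
  )
}

#' Expanding-window one-step-ahead forecasts for a model set
#'
#' For every target year `y` in the evaluation window and every registered
#' model, builds a forecast using ONLY data through year `y - 1` (strict
#' no-look-ahead): the wetland covariate is re-standardized from history
#' alone (recursive mode, the default), the persistence sd and the
#' wetland-model posterior are re-estimated on the expanding window, and
#' the AHM models are driven by the previous year's abundance, wetlands
#' and harvest rates.
#'
#' The wetland null model defers to the persistence forecast until it has
#' at least three growth observations (identical information sets at the
#' series start). Target years with no observation are forecast but
#' excluded from scoring (observed = NA) with a message.
#'
#' @param data list with elements `abundance` ([abundance_series()]),
#'   `wetland` ([wetland_series()]), and (if any AHM model is registered)
#'   `harvest` ([harvest_series()]).
#' @param models character vector drawn from
#'   `c(ahm_model_ids(), "persistence", "wetland")`.
#' @param eval_years length-2 integer vector `c(first, last)` of target
#'   years to forecast.
#' @param ahm_params AHM parameters, as [default_ahm_params()].
#' @param prior wetland-model prior, as [wetland_prior()].
#' @param standardization `"recursive"` (default), `"all"`, or a fixed
#'   year range, passed to [standardize_wetlands()] on each history window.
#' @param use_obs_error if `TRUE` and the abundance series carries survey
#'   SEs, the most recent SE is folded into each AHM predictive sd.
#' @return A data frame of class `forecast_table`: one row per
#'   (model, target year) with the record columns plus `observed`.
#' @export
run_one_step_ahead <- function(data, models, eval_years,
                               ahm_params = default_ahm_params(),
                               prior = wetland_prior(),
                               standardization = "recursive",
                               use_obs_error = TRUE) {
  stopifnot(length(eval_years) == 2, eval_years[1] <= eval_years[2])
  known <- c(ahm_model_ids(), "persistence", "wetland")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  abund <- data$abundance
  if (min(abund$year) >= eval_years[1]) {
    stop("evaluation window must start after the first data year",
         call. = FALSE)
  }
  ahm <- intersect(models, ahm_model_ids())
  if (length(ahm) && is.null(data$harvest)) {
    stop("AHM models require a harvest series", call. = FALSE)
  }
  rows <- list()
  for (y in seq(eval_years[1], eval_years[2])) {
    hist_n <- abund[abund$year <= y - 1, , drop = FALSE]
    if (!(y - 1) %in% hist_n$year) next  # cannot forecast across a gap
    obs <- if (y %in% abund$year) abund$N[abund$year == y] else NA_real_
    if (is.na(obs)) {
      message("no observation for target year ", y,
              "; forecast made but excluded from scoring")
    }
    hist_w <- data$wetland[data$wetland$year <= y - 1, , drop = FALSE]
    w_std <- standardize_wetlands(
      structure(hist_w, class = class(data$wetland)), standardization)
    N_t <- hist_n$N[nrow(hist_n)]
    for (m in models) {
      rec <- forecast_one(m, y, hist_n, w_std, data$harvest, ahm_params,
                          prior, use_obs_error)
      rec$observed <- obs
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("forecast_table", "data.frame"))
}

forecast_one <- function(model_id, y, hist_n, w_std, harvest, ahm_params,
                         prior, use_obs_error) {
  if (model_id == "persistence") {
    return(persistence_forecast(hist_n, target_year = y))
  }
  N_t <- hist_n$N[nrow(hist_n)]
  x_t <- w_std$W_std[w_std$year == y - 1]
  if (length(x_t) != 1 || is.na(x_t)) {
    if (model_id == "wetland") {
      return(fallback_persistence(hist_n, y, "wetland"))
    }
    stop("no standardizable wetland value for year ", y - 1, call. = FALSE)
  }
  if (model_id == "wetland") {
    growth <- growth_observations(hist_n, w_std)
    if (nrow(growth) < 3) return(fallback_persistence(hist_n, y, "wetland"))
    post <- fit_wetland_model(hist_n, w_std, prior)
    return(wetland_forecast(post, N_t, x_t, target_year = y))
  }
  h_row <- harvest[harvest$year == y - 1, , drop = FALSE]
  if (nrow(h_row) != 1) {
    stop("no harvest rates for year ", y - 1, call. = FALSE)
  }
  h <- c(am = h_row$k_am, af = h_row$k_af, jm = h_row$k_jm, jf = h_row$k_jf)
  obs_sd <- NULL
  if (use_obs_error && "se" %in% names(hist_n)) {
    se_known <- hist_n$se[!is.na(hist_n$se)]
    if (length(se_known)) obs_sd <- se_known[length(se_known)]
  }
  ahm_forecast(model_id, N_t, x_t, h, ahm_params, target_year = y,
               obs_sd = obs_sd)
}

fallback_persistence <- function(hist_n, y, model_id) {
  rec <- persistence_forecast(hist_n, target_year = y)
  rec$model_id <- model_id
  rec
}

#' Model-averaged forecast for one year
#'
#' Finite mixture of the supplied records under the given weights: the
#' stored mean is `sum(w_i * mean_i)` and the stored sd comes from the
#' mixture variance `sum(w_i * (sd_i^2 + mean_i^2)) - mean^2`.
#'
#' @param records `forecast_table` rows for a single target year.
#' @param weights named numeric weights summing to 1, names matching
#'   `records$model_id` exactly.
#' @param model_id identifier for the averaged record.
#' @return A one-row `forecast_record` with family `"mixture"`.
#' @export
model_average <- function(records, weights, model_id = "AHMavg") {
  if (length(unique(records$target_year)) != 1) {
    stop("records must share one target year", call. = FALSE)
  }
  if (!setequal(names(weights), records$model_id) ||
      length(weights) != nrow(records)) {
    stop("weights must cover exactly the supplied models", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  w <- weights[records$model_id]
  mu <- sum(w * records$mean)
  v <- sum(w * (records$sd^2 + records$mean^2)) - mu^2
  forecast_record(model_id, records$target_year[1], family = "mixture",
                  mean = mu, sd = sqrt(max(v, 0)))
}
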