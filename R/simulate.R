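# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic study scenario
#'
#' Defines the data-generating conditions for a synthetic abundance /
#' wetland / harvest bundle with the statistical structure the analysis
#' assumes: a latent abundance series propagated by one of the candidate
#' models with multiplicative lognormal process noise, a stationary AR(1)
#' pond series on the log scale, i.i.d. truncated-normal harvest rates per
#' age-sex class, and multiplicative lognormal (or additive normal)
#' survey observation error.
#'
#' Defaults emulate the midcontinent mallard system at the scale of the
#' USFWS survey: ~8 million breeding birds, ~4 million May ponds with
#' lag-1 autocorrelation 0.7, mean harvest rates of 7-15% by class,
#' process sd 0.05 on the log scale and survey CV 0.05.
#'
#' @param generator generating model: one of [ahm_model_ids()],
#'   `"persistence"`, or `"wetland"` (the wetland-growth null).
#' @param n_years series length (>= 5).
#' @param N0 initial abundance (millions).
#' @param start_year first calendar year.
#' @param beta wetland-growth coefficient (used when
#'   `generator = "wetland"`).
#' @param process_sd log-scale sd of the process noise.
#' @param wetland list: `mean` (millions of ponds, the median of the
#'   lognormal AR(1)), `phi` autocorrelation in (-1, 1), `sd` log-scale
#'   innovation sd.
#' @param harvest list: `mean` named per-class means, `sd` common sd,
#'   `lower`/`upper` truncation bounds within \[0, 1).
#' @param obs list: `type` `"lognormal"` (with `cv`) or `"normal"` (with
#'   `sd`, millions).
#' @param ahm AHM submodel parameters, as [default_ahm_params()].
#' @param seed integer seed; all draws are reproducible from it.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(generator = "SaRw", n_years = 40, N0 = 8,
                          start_year = 1980L, beta = 0.1,
                          process_sd = 0.05,
                          wetland = list(mean = 4, phi = 0.7, sd = 0.25),
                          harvest = list(
                            mean = c(am = 0.10, af = 0.07,
                                     jm = 0.15, jf = 0.10),
                            sd = 0.02, lower = 0, upper = 0.35),
                          obs = list(type = "lognormal", cv = 0.05),
                          ahm = default_ahm_params(), seed = 1L) {
  known <- c(ahm_model_ids(), "persistence", "wetland")
  if (!generator %in% known) {
    stop("unknown generator: ", generator, call. = FALSE)
  }
  if (n_years < 5) stop("n_years must be >= 5", call. = FALSE)
  if (abs(wetland$phi) >= 1) {
    stop("wetland autocorrelation phi must satisfy |phi| < 1",
         call. = FALSE)
  }
  if (wetland$sd < 0 || process_sd < 0 || harvest$sd < 0) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  if (harvest$lower < 0 || harvest$upper >= 1 ||
      harvest$lower >= harvest$upper) {
    stop("harvest bounds must satisfy 0 <= lower < upper < 1",
         call. = FALSE)
  }
  if (identical(obs$type, "lognormal") && (is.null(obs$cv) || obs$cv < 0)) {
    stop("lognormal observation error needs a nonnegative cv",
         call. = FALSE)
  }
  structure(list(generator = generator, n_years = as.integer(n_years),
                 N0 = N0, start_year = as.integer(start_year), beta = beta,
                 process_sd = process_sd, wetland = wetland,
                 harvest = harvest, obs = obs, ahm = ahm,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate a wetland (pond) series
#'
#' Stationary AR(1) on the log scale, exponentiated: the first year is
#' drawn from the stationary distribution, so the series has no burn-in
#' transient. Zero innovation sd gives a constant series at the mean.
#'
#' @param spec a [scenario_spec()].
#' @return A [wetland_series()].
#' @export
simulate_wetlands <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  local_seed(spec$seed + 1L, {
    n <- spec$n_years
    mu <- log(spec$wetland$mean)
    phi <- spec$wetland$phi
    s <- spec$wetland$sd
    x <- numeric(n)
    if (s == 0) {
      x[] <- mu
    } else {
      x[1] <- stats::rnorm(1, mu, s / sqrt(1 - phi^2))
      for (t in seq_len(n - 1)) {
        x[t + 1] <- mu + phi * (x[t] - mu) + stats::rnorm(1, 0, s)
      }
    }
    wetland_series(spec$start_year + seq_len(n) - 1L, exp(x))
  })
}

#' Simulate per-class harvest rates
#'
#' Independent truncated-normal draws per class and year (no
#' harvest-policy feedback on density).
#'
#' @param spec a [scenario_spec()].
#' @return A [harvest_series()].
#' @export
simulate_harvest <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  local_seed(spec$seed + 2L, {
    n <- spec$n_years
    hp <- spec$harvest
    draw <- function(mu) {
      if (hp$sd == 0) return(rep(mu, n))
      lo <- stats::pnorm(hp$lower, mu, hp$sd)
      hi <- stats::pnorm(hp$upper, mu, hp$sd)
      stats::qnorm(stats::runif(n, lo, hi), mu, hp$sd)
    }
    harvest_series(spec$start_year + seq_len(n) - 1L,
                   k_am = draw(hp$mean[["am"]]), k_af = draw(hp$mean[["af"]]),
                   k_jm = draw(hp$mean[["jm"]]), k_jf = draw(hp$mean[["jf"]]))
  })
}

#' Simulate a full abundance / wetland / harvest scenario
#'
#' Propagates a latent abundance series under the chosen generating model
#' with multiplicative lognormal process noise, then overlays survey
#' observation error. Wetlands entering the generator dynamics are
#' standardized with a fixed baseline over the whole simulated series
#' (the generator's truth; recorded in the returned bundle), while the
#' forecasting pipeline may re-standardize recursively.
#'
#' Generator dynamics for the step from t to t+1 (before process noise):
#' * AHM models — the balance equation with that year's harvest rates and
#'   standardized wetlands;
#' * `"persistence"` — `N_t` (a lognormal random walk once noise is
#'   added);
#' * `"wetland"` — `N_t * exp(beta * W_std_t)` (equilibrium growth rate
#'   zero).
#'
#' @param spec a [scenario_spec()].
#' @return A list of class `ahm_scenario`: `abundance` (observed, with
#'   `se` when the observation model is lognormal), `truth` (latent
#'   abundance), `wetland`, `harvest`, `w_std` (the fixed-baseline
#'   standardization used by the generator), and `spec`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  wet <- simulate_wetlands(spec)
  harv <- simulate_harvest(spec)
  w_std <- standardize_wetlands(wet, baseline = "all")
  n <- spec$n_years
  years <- spec$start_year + seq_len(n) - 1L
  latent <- numeric(n)
  latent[1] <- spec$N0
  local_seed(spec$seed + 3L, {
    eps <- stats::rnorm(n - 1, 0, spec$process_sd)
    for (t in seq_len(n - 1)) {
      step <- generator_step(spec, latent[t], w_std$W_std[t],
                             harv[t, , drop = FALSE])
      latent[t + 1] <- step * exp(eps[t])
      if (!is.finite(latent[t + 1]) || latent[t + 1] < 1e-3 ||
          latent[t + 1] > 1e3) {
        stop("latent abundance left [1e-3, 1e3] million in year ",
             years[t + 1], "; parameterization unstable", call. = FALSE)
      }
    }
  })
  obs <- local_seed(spec$seed + 4L, {
    if (identical(spec$obs$type, "lognormal")) {
      sdlog <- sqrt(log(1 + spec$obs$cv^2))
      N_obs <- latent * exp(stats::rnorm(n, 0, sdlog))
      abundance_series(years, N_obs, se = spec$obs$cv * N_obs)
    } else {
      N_obs <- latent + stats::rnorm(n, 0, spec$obs$sd)
      if (any(N_obs <= 0)) {
        stop("additive observation noise produced nonpositive abundance",
             call. = FALSE)
      }
      abundance_series(years, N_obs)
    }
  })
  structure(list(abundance = obs,
                 truth = abundance_series(years, latent),
                 wetland = wet, harvest = harv, w_std = w_std, spec = spec),
            class = "ahm_scenario")
}

generator_step <- function(spec, N_t, w_std_t, harv_row) {
  g <- spec$generator
  if (g == "persistence") return(N_t)
  if (g == "wetland") return(N_t * exp(spec$beta * w_std_t))
  parts <- parse_model_id(g)
  h <- c(am = harv_row$k_am, af = harv_row$k_af,
         jm = harv_row$k_jm, jf = harv_row$k_jf)
  surv <- class_survival(parts$survival, h, spec$ahm$survival)
  R_t <- reproduction_rate(spec$ahm$repro[[parts$repro]], N_t, w_std_t)
  balance_step(N_t, surv, R_t, spec$ahm$balance)
}

#' Write a simulated scenario to disk
#'
#' Emits the three standard CSVs (`abundance.csv`, `wetland.csv`,
#' `harvest.csv`) plus `truth.json` recording every true parameter, the
#' generator id, the seed, and the latent abundance series.
#'
#' @param bundle an `ahm_scenario` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ahm_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.csv"),
             wetland = file.path(dir, "wetland.csv"),
             harvest = file.path(dir, "harvest.csv"),
             truth = file.path(dir, "truth.json"))
  write_series(bundle$abundance, paths[["abundance"]])
  write_series(bundle$wetland, paths[["wetland"]])
  write_series(bundle$harvest, paths[["harvest"]])
  truth <- bundle$spec
  truth$latent_N <- bundle$truth$N
  truth$years <- bundle$truth$year
  truth$wetland_std_baseline <- list(
    mean = attr(bundle$w_std, "baseline_mean"),
    sd = attr(bundle$w_std, "baseline_sd"))
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
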