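#' Default AHM submodel parameters
#'
#' Illustrative (synthetic) parameter values for the four mechanistic AHM
#' models. These are NOT the official USFWS coefficients, which live in
#' agency reports; they are chosen so that the weak/strong
#' density-dependence models have equilibria in the 8-10 million-bird range
#' typical of the midcontinent mallard breeding population. All values can
#' be overridden via the YAML run configuration.
#'
#' Components:
#' * `survival`: `s0` per-class annual survival in the absence of hunting,
#'   `crippling_loss` fraction converting harvest rate to kill rate.
#' * `repro`: intercept `a0` (young per adult female), abundance slope `a1`
#'   (per million birds, <= 0; the weak/strong hypotheses differ only in
#'   its magnitude), wetland slope `a2` (per z-unit, >= 0).
#' * `balance`: bias-correction multipliers `gamma_S`, `gamma_R` (1 = no
#'   correction), male proportion `m`, female:male summer-survival ratio
#'   `phi_ratio`, and log-scale `process_sd` of the lognormal process noise.
#'
#' @return A nested list of parameter values.
#' @export
default_ahm_params <- function() {
  list(
    survival = list(
      s0 = c(am = 0.85, af = 0.75, jm = 0.80, jf = 0.70),
      crippling_loss = 0.2
    ),
    repro = list(
      weak   = list(a0 = 1.00, a1 = -0.05, a2 = 0.2),
      strong = list(a0 = 1.75, a1 = -0.15, a2 = 0.2)
    ),
    balance = list(
      gamma_S = 1, gamma_R = 1, m = 0.55, phi_ratio = 0.9,
      process_sd = 0.05
    )
  )
}

#' The four AHM model identifiers
#' @return `c("SaRw", "SaRs", "ScRw", "ScRs")`: additive (Sa) or
#'   compensatory (Sc) harvest mortality crossed with weak (Rw) or strong
#'   (Rs) density-dependent reproduction.
#' @export
ahm_model_ids <- function() c("SaRw", "SaRs", "ScRw", "ScRs")

#' Kill rate from harvest rate and crippling loss
#'
#' The per-capita probability of death from harvest inflates the harvest
#' (band-recovery) rate for unretrieved kill: `K = h / (1 - c)`.
#'
#' @param h harvest rate(s) in \[0, 1).
#' @param c crippling-loss fraction in \[0, 1).
#' @return Kill rate(s) in \[0, 1).
#' @export
kill_rate <- function(h, c = 0) {
  stopifnot(all(h >= 0), all(h < 1), c >= 0, c < 1)
  K <- h / (1 - c)
  if (any(K >= 1)) {
    stop("kill rate >= 1: harvest rate ", max(h), " with crippling loss ",
         c, " implies total kill exceeding the population", call. = FALSE)
  }
  K
}

#' Annual survival under the additive harvest-mortality hypothesis
#'
#' Harvest mortality adds fully to natural mortality: `S = s0 * (1 - K)`,
#' strictly decreasing in the kill rate.
#'
#' @param s0 survival in the absence of hunting, in (0, 1\].
#' @param K kill rate(s) in \[0, 1).
#' @return Survival probability(ies).
#' @export
survival_additive <- function(s0, K) {
  stopifnot(all(s0 > 0), all(s0 <= 1), all(K >= 0), all(K < 1))
  s0 * (1 - K)
}

#' Annual survival under the compensatory harvest-mortality hypothesis
#'
#' Completely-compensatory threshold form (Anderson-Burnham): natural
#' mortality declines to offset harvest up to the threshold `C = 1 - s0`,
#' so `S = s0` for `K <= C` and `S = 1 - K` beyond it; continuous at the
#' threshold.
#'
#' @inheritParams survival_additive
#' @return Survival probability(ies).
#' @export
survival_compensatory <- function(s0, K) {
  stopifnot(all(s0 > 0), all(s0 <= 1), all(K >= 0), all(K < 1))
  pmin(s0, 1 - K)
}

#' Annual reproductive rate
#'
#' Young per adult female as a linear function of breeding abundance and
#' standardized wetland availability, truncated at zero:
#' `R = max(0, a0 + a1 * N + a2 * W_std)`. The weak and strong
#' density-dependence hypotheses use the same form with different `a1`.
#'
#' @param repro list with elements `a0`, `a1`, `a2`.
#' @param N_t breeding abundance (millions), > 0.
#' @param W_std standardized wetland abundance (z-score).
#' @return Reproductive rate >= 0.
#' @export
reproduction_rate <- function(repro, N_t, W_std) {
  stopifnot(N_t > 0)
  max(0, repro$a0 + repro$a1 * N_t + repro$a2 * W_std)
}

#' One annual step of the AHM balance equation
#'
#' Age- and sex-structured projection of spring abundance:
#' `N_{t+1} = gamma_S * N_t * [ m * S_am +
#'   (1 - m) * ( S_af + gamma_R * R_t * ( S_jf + S_jm * phi_ratio ) ) ]`
#' where recruitment is produced by the adult-female share and
#' `phi_ratio = phi_f^sum / phi_m^sum` converts juvenile males through the
#' summer-survival sex ratio.
#'
#' @param N_t spring abundance (millions), > 0.
#' @param surv named numeric with elements `am`, `af`, `jm`, `jf`: annual
#'   survival per age-sex class, each in \[0, 1\].
#' @param R_t reproductive rate (young per adult female), >= 0.
#' @param balance list with `gamma_S`, `gamma_R`, `m`, `phi_ratio`.
#' @return Expected abundance at `t + 1` (millions), > 0.
#' @export
balance_step <- function(N_t, surv, R_t, balance) {
  stopifnot(N_t > 0, R_t >= 0,
            all(c("am", "af", "jm", "jf") %in% names(surv)),
            all(surv >= 0), all(surv <= 1),
            balance$gamma_S > 0, balance$gamma_R > 0,
            balance$m > 0, balance$m < 1, balance$phi_ratio > 0)
  out <- balance$gamma_S * N_t *
    (balance$m * surv[["am"]] +
       (1 - balance$m) *
         (surv[["af"]] +
            balance$gamma_R * R_t *
              (surv[["jf"]] + surv[["jm"]] * balance$phi_ratio)))
  if (!is.finite(out) || out <= 0) {
    stop("balance equation produced a nonpositive abundance; ",
         "parameterization inconsistent", call. = FALSE)
  }
  out
}

#' Class-specific survival under one AHM survival hypothesis
#'
#' @param hypothesis `"additive"` or `"compensatory"`.
#' @param h named numeric harvest rates (`am`, `af`, `jm`, `jf`).
#' @param survival list with `s0` (named per-class) and `crippling_loss`.
#' @return Named numeric survival per class.
#' @export
class_survival <- function(hypothesis = c("additive", "compensatory"),
                           h, survival) {
  hypothesis <- match.arg(hypothesis)
  classes <- c("am", "af", "jm", "jf")
  stopifnot(all(classes %in% names(h)), all(classes %in% names(survival$s0)))
  K <- vapply(classes, function(cl)
    kill_rate(h[[cl]], survival$crippling_loss), numeric(1))
  fn <- if (hypothesis == "additive") survival_additive else
    survival_compensatory
  vapply(classes, function(cl) fn(survival$s0[[cl]], K[[cl]]), numeric(1))
}

parse_model_id <- function(model_id) {
  if (!model_id %in% ahm_model_ids()) {
    stop("unknown AHM model id: ", model_id, call. = FALSE)
  }
  list(
    survival = if (substr(model_id, 2, 2) == "a") "additive" else
      "compensatory",
    repro = if (substr(model_id, 4, 4) == "w") "weak" else "strong"
  )
}

#' One-step-ahead forecast from an AHM model
#'
#' Runs the chosen survival and reproduction submodels through the balance
#' equation and wraps the result in a lognormal predictive distribution
#' whose median equals the balance-equation output and whose log-scale sd
#' is `process_sd`; a survey observation sd, when supplied, is added on the
#' variance scale of the matching normal (log) approximation.
#'
#' @param model_id one of [ahm_model_ids()].
#' @param N_t abundance at year t (millions).
#' @param W_std_t standardized wetland abundance at year t.
#' @param harvest_t named numeric harvest rates at year t.
#' @param params parameter list as from [default_ahm_params()].
#' @param target_year calendar year being forecast (t + 1).
#' @param obs_sd optional survey observation sd (millions) folded into the
#'   predictive spread.
#' @return A one-row `forecast_record` data frame.
#' @export
ahm_forecast <- function(model_id, N_t, W_std_t, harvest_t,
                         params = default_ahm_params(),
                         target_year = NA_integer_, obs_sd = NULL) {
  parts <- parse_model_id(model_id)
  surv <- class_survival(parts$survival, harvest_t, params$survival)
  R_t <- reproduction_rate(params$repro[[parts$repro]], N_t, W_std_t)
  med <- balance_step(N_t, surv, R_t, params$balance)
  sdlog <- params$balance$process_sd
  if (!is.null(obs_sd) && is.finite(obs_sd) && obs_sd > 0) {
    sdlog <- sqrt(sdlog^2 + (obs_sd / med)^2)
  }
  forecast_record(model_id, target_year, family = "lognormal",
                  par1 = log(med), par2 = sdlog)
}
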