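#' Population-persistence forecast
#'
#' The "tomorrow resembles today" ecological null model: the predictive
#' mean for year t+1 equals the observed abundance at t exactly, and the
#' predictive sd is the sample sd of all one-step differences in the
#' history (additive normal noise, N_{t+1} = N_t + eps). With a single
#' difference the sd is its absolute value; a constant history gives sd 0.
#'
#' @param history an [abundance_series()] through year t (>= 2 years).
#' @param target_year calendar year being forecast.
#' @return A one-row `forecast_record` with family `"normal"`.
#' @export
persistence_forecast <- function(history, target_year = NA_integer_) {
  if (nrow(history) < 2) {
    stop("persistence forecast needs at least 2 years of history",
         call. = FALSE)
  }
  d <- diff(history$N)
  sigma <- if (length(d) == 1) abs(d) else stats::sd(d)
  forecast_record("persistence", target_year, family = "normal",
                  par1 = history$N[nrow(history)], par2 = sigma)
}

#' Prior for the wetland growth model
#'
#' Normal-inverse-gamma prior for the regression of annual log growth
#' rates on standardized wetlands through the origin (the equilibrium
#' growth rate r_eq is fixed at 0, so no intercept is estimated):
#' beta | sigma^2 ~ Normal(`beta_mean`, sigma^2 * `beta_scale`),
#' sigma^2 ~ InvGamma(`a`, `b`). Defaults are vague. Setting `fixed_beta`
#' pins beta to a constant (a point-mass prior); only sigma^2 is then
#' updated.
#'
#' @param beta_mean prior mean of the wetland coefficient.
#' @param beta_scale prior scale factor on the coefficient variance.
#' @param a,b inverse-gamma shape and rate for sigma^2.
#' @param fixed_beta optional constant value pinning beta.
#' @return A list of class `wetland_prior`.
#' @export
wetland_prior <- function(beta_mean = 0, beta_scale = 100,
                          a = 0.01, b = 0.01, fixed_beta = NULL) {
  stopifnot(beta_scale > 0, a > 0, b > 0)
  structure(list(beta_mean = beta_mean, beta_scale = beta_scale,
                 a = a, b = b, fixed_beta = fixed_beta),
            class = "wetland_prior")
}

#' Paired growth observations for the wetland model
#'
#' Builds the regression data: response `y = log(N_{s+1} / N_s)` for every
#' consecutive pair of observed years, paired with the standardized
#' wetland value at year s. Pairs spanning a gap or an unstandardizable
#' wetland year are dropped.
#'
#' @param history_N an [abundance_series()].
#' @param history_W a `standardized_wetlands` data frame.
#' @return Data frame with columns `year` (s), `x` (W_std at s), `y`.
#' @export
growth_observations <- function(history_N, history_W) {
  yrs <- history_N$year
  keep <- which(diff(yrs) == 1L)
  out <- data.frame(
    year = yrs[keep],
    x = history_W$W_std[match(yrs[keep], history_W$year)],
    y = log(history_N$N[keep + 1L] / history_N$N[keep])
  )
  out[!is.na(out$x) & is.finite(out$y), , drop = FALSE]
}

#' Fit the wetland growth null model
#'
#' Conjugate Bayesian update of the normal-inverse-gamma prior for the
#' no-intercept regression of log growth rate on standardized wetlands,
#' using all growth observations available through year t. Deterministic
#' given its inputs; refitting sequentially (posterior as next prior)
#' reproduces the batch fit exactly (conjugacy).
#'
#' @param history_N an [abundance_series()] through year t.
#' @param history_W a `standardized_wetlands` covering the same years.
#' @param prior a [wetland_prior()].
#' @return An object of class `wetland_posterior`: posterior `beta_mean`,
#'   `beta_scale` (V_n), inverse-gamma `a`, `b`, `df = 2a`, the marginal
#'   posterior sd of beta (`beta_sd`), and `n_obs`.
#' @export
fit_wetland_model <- function(history_N, history_W, prior = wetland_prior()) {
  g <- growth_observations(history_N, history_W)
  if (nrow(g) < 3) {
    stop("wetland model needs at least 3 growth observations (got ",
         nrow(g), ")", call. = FALSE)
  }
  update_nig(prior, g$x, g$y, n_prev = 0L)
}

# One conjugate NIG update step; shared by batch and sequential paths.
update_nig <- function(prior, x, y, n_prev = 0L) {
  n <- length(y)
  if (!is.null(prior$fixed_beta)) {
    beta <- prior$fixed_beta
    a_n <- prior$a + n / 2
    b_n <- prior$b + sum((y - beta * x)^2) / 2
    post <- wetland_prior(beta_mean = beta, beta_scale = prior$beta_scale,
                          a = a_n, b = b_n, fixed_beta = beta)
    post$beta_var_factor <- 0
  } else {
    V0 <- prior$beta_scale
    m0 <- prior$beta_mean
    V_n <- 1 / (1 / V0 + sum(x^2))
    m_n <- V_n * (m0 / V0 + sum(x * y))
    a_n <- prior$a + n / 2
    b_n <- prior$b + (sum(y^2) + m0^2 / V0 - m_n^2 / V_n) / 2
    post <- wetland_prior(beta_mean = m_n, beta_scale = V_n,
                          a = a_n, b = b_n)
    post$beta_var_factor <- V_n
  }
  post$df <- 2 * post$a
  scale2 <- (post$b / post$a) * post$beta_var_factor
  post$beta_sd <- if (post$df > 2) {
    sqrt(scale2 * post$df / (post$df - 2))
  } else {
    sqrt(scale2)
  }
  post$sigma2_mean <- if (post$a > 1) post$b / (post$a - 1) else NA_real_
  post$n_obs <- n_prev + n
  class(post) <- c("wetland_posterior", "wetland_prior")
  post
}

#' Sequentially update a wetland-model posterior with new data
#'
#' @param post a `wetland_posterior` (or [wetland_prior()]).
#' @param x,y new regressor/response pairs.
#' @return Updated `wetland_posterior`.
#' @export
update_wetland_model <- function(post, x, y) {
  update_nig(post, x, y, n_prev = if (is.null(post$n_obs)) 0L else post$n_obs)
}

#' One-step-ahead forecast from the wetland growth model
#'
#' Posterior-predictive distribution of `log N_{t+1}` is Student-t with
#' location `log N_t + beta_hat * W_std_t`, scale from the posterior
#' predictive (residual plus parameter uncertainty) and df equal to the
#' posterior degrees of freedom. The record stores moment summaries on the
#' abundance scale via the moment-matched normal approximation of the
#' log-scale t (see [forecast_record()]); weight updating evaluates the
#' exact t density.
#'
#' @param post a `wetland_posterior` from [fit_wetland_model()].
#' @param N_t abundance at year t (millions).
#' @param W_std_t standardized wetland value at year t.
#' @param target_year calendar year being forecast.
#' @return A one-row `forecast_record` with family `"student-t"`.
#' @export
wetland_forecast <- function(post, N_t, W_std_t, target_year = NA_integer_) {
  stopifnot(inherits(post, "wetland_posterior"), N_t > 0)
  loc <- log(N_t) + post$beta_mean * W_std_t
  scale <- sqrt((post$b / post$a) *
                  (1 + W_std_t^2 * post$beta_var_factor))
  forecast_record("wetland", target_year, family = "student-t",
                  par1 = loc, par2 = scale, par3 = post$df)
}
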