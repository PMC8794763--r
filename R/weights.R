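#' Uniform initial model weights
#'
#' Complete structural uncertainty conditional on the candidate set: each
#' of k models receives weight 1/k (0.25 each for the four AHM models).
#'
#' @param model_ids character vector of model identifiers.
#' @return Named numeric weight vector summing to 1.
#' @export
init_weights <- function(model_ids) {
  if (length(model_ids) < 1) stop("empty model set", call. = FALSE)
  if (anyDuplicated(model_ids)) stop("duplicate model ids", call. = FALSE)
  stats::setNames(rep(1 / length(model_ids), length(model_ids)), model_ids)
}

#' One Bayesian update of model weights
#'
#' Applies Bayes' theorem with each model's predictive density evaluated
#' at the new observation: `w_i' = w_i * f_i(obs) / sum_j w_j * f_j(obs)`.
#' Computation is in log space for numerical stability. Degenerate
#' (sd = 0) forecasts are treated as point masses: such a model keeps
#' weight only if the observation matches its mean to within 1e-9
#' (reported with a warning).
#'
#' @param w named numeric weights (nonnegative, summing to 1).
#' @param forecasts `forecast_table` rows for a single year, covering
#'   exactly the weighted models.
#' @param obs observed abundance at that year (millions), > 0.
#' @return Updated named weight vector summing to 1.
#' @export
update_weights <- function(w, forecasts, obs) {
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(w), forecasts$model_id) ||
      nrow(forecasts) != length(w)) {
    stop("forecasts must cover exactly the weighted models", call. = FALSE)
  }
  forecasts <- forecasts[match(names(w), forecasts$model_id), , drop = FALSE]
  logf <- vapply(seq_len(nrow(forecasts)), function(i)
    forecast_log_density(forecasts[i, , drop = FALSE], obs), numeric(1))
  if (any(is.infinite(logf) & logf > 0)) {
    warning("degenerate (sd = 0) forecast matched the observation; ",
            "weight assigned as a point mass", call. = FALSE)
    hit <- is.infinite(logf) & logf > 0 & w > 0
    w_new <- ifelse(hit, w, 0)
    return(w_new / sum(w_new))
  }
  logw <- log(w) + logf
  m <- max(logw)
  if (!is.finite(m)) {
    stop("all model likelihoods are zero (or underflowed) at observation ",
         obs, "; cannot update weights", call. = FALSE)
  }
  w_new <- exp(logw - m)
  w_new / sum(w_new)
}

#' Iterative weight trajectory over a forecast table
#'
#' Sequentially applies [update_weights()] in year order over every scored
#' year (those with an observation), starting from `init`. The row for
#' year y holds the posterior weights AFTER observing year y; the weights
#' available at the start of year y are therefore the previous row (or
#' `init` for the first scored year).
#'
#' @param table a `forecast_table` containing forecasts for all weighted
#'   models in all scored years.
#' @param init named initial weights, as [init_weights()].
#' @return A data frame of class `weight_series`: column `year` plus one
#'   weight column per model; attribute `init` stores the starting
#'   weights.
#' @export
weight_trajectory <- function(table, init) {
  sub <- table[table$model_id %in% names(init), , drop = FALSE]
  years <- sort(unique(sub$target_year[!is.na(sub$observed)]))
  w <- init
  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    rows_y <- sub[sub$target_year == years[i], , drop = FALSE]
    w <- update_weights(w, rows_y, rows_y$observed[1])
    rows[[i]] <- c(year = years[i], w)
  }
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, init = init,
            class = c("weight_series", "data.frame"))
}
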