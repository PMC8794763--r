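#' Root mean square forecast error
#'
#' @param pred,obs aligned numeric vectors (predicted means and observed
#'   abundances, millions).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  check_pairs(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' Normalized RMSE
#'
#' RMSE divided by the mean observed abundance over the scored years;
#' unitless, invariant to rescaling of the abundance units.
#'
#' @inheritParams rmse
#' @return Unitless score >= 0.
#' @export
nrmse <- function(pred, obs) {
  check_pairs(pred, obs)
  if (mean(obs) <= 0) stop("mean of observations must be positive",
                           call. = FALSE)
  rmse(pred, obs) / mean(obs)
}

#' Mean signed difference
#'
#' `mean(pred - obs)`: negative values indicate systematic
#' underprediction.
#'
#' @inheritParams rmse
#' @return Signed score (millions).
#' @export
msd <- function(pred, obs) {
  check_pairs(pred, obs)
  mean(pred - obs)
}

#' Normalized mean signed difference
#'
#' `mean(pred - obs) / mean(obs)`: a unitless, signed measure of
#' systematic forecast bias (the tell-tale sign of a misspecified model).
#' Negative values indicate underprediction.
#'
#' @inheritParams rmse
#' @return Unitless signed score.
#' @export
nmsd <- function(pred, obs) {
  check_pairs(pred, obs)
  if (mean(obs) <= 0) stop("mean of observations must be positive",
                           call. = FALSE)
  msd(pred, obs) / mean(obs)
}

check_pairs <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("`pred` and `obs` must have equal length", call. = FALSE)
  }
  if (length(pred) < 1) stop("need at least one forecast/observation pair",
                             call. = FALSE)
  if (any(!is.finite(pred)) || any(!is.finite(obs))) {
    stop("non-finite values in forecasts or observations", call. = FALSE)
  }
  invisible(TRUE)
}

#' Skill report for a forecast table against a null benchmark
#'
#' Computes RMSE/NRMSE/MSD/NMSD per model over the common scored years
#' (years where every model has a forecast and an observation exists) and
#' benchmark ratios against a designated null model:
#' `ratio_nmsd = |nmsd_model| / |nmsd_null|` and
#' `ratio_nrmse = nrmse_model / nrmse_null`. A model whose `ratio_nmsd`
#' exceeds 1 is flagged as failing the null benchmark. A null with NMSD
#' exactly 0 gives infinite ratios, flagged rather than erroring.
#'
#' @param table a `forecast_table` from [run_one_step_ahead()].
#' @param null_id model id of the benchmark null (must be in the table).
#' @return A data frame of class `skill_scores`: one row per model with
#'   columns `model_id`, `n_years`, `rmse`, `nrmse`, `msd`, `nmsd`,
#'   `ratio_nrmse`, `ratio_nmsd`, `fails_null`, plus attribute
#'   `null_degenerate` when the null NMSD is 0.
#' @export
skill_report <- function(table, null_id = "persistence") {
  models <- unique(table$model_id)
  if (!null_id %in% models) {
    stop("null model `", null_id, "` not present in the table",
         call. = FALSE)
  }
  scored <- table[!is.na(table$observed), , drop = FALSE]
  year_counts <- vapply(split(scored$model_id, scored$target_year),
                        length, integer(1))
  common <- as.integer(names(year_counts)[year_counts == length(models)])
  if (length(common) < 1) {
    stop("no common scored years across models", call. = FALSE)
  }
  scored <- scored[scored$target_year %in% common, , drop = FALSE]
  per_model <- lapply(models, function(m) {
    rows <- scored[scored$model_id == m, , drop = FALSE]
    rows <- rows[order(rows$target_year), , drop = FALSE]
    data.frame(model_id = m, n_years = nrow(rows),
               rmse = rmse(rows$mean, rows$observed),
               nrmse = nrmse(rows$mean, rows$observed),
               msd = msd(rows$mean, rows$observed),
               nmsd = nmsd(rows$mean, rows$observed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_model)
  null_nmsd <- abs(out$nmsd[out$model_id == null_id])
  null_nrmse <- out$nrmse[out$model_id == null_id]
  degenerate <- null_nmsd == 0
  out$ratio_nrmse <- if (null_nrmse == 0) {
    ifelse(out$nrmse == 0, 1, Inf)
  } else {
    out$nrmse / null_nrmse
  }
  out$ratio_nmsd <- if (degenerate) {
    ifelse(abs(out$nmsd) == 0, 1, Inf)
  } else {
    abs(out$nmsd) / null_nmsd
  }
  out$fails_null <- out$ratio_nmsd > 1
  rownames(out) <- NULL
  structure(out, null_id = null_id, null_degenerate = degenerate,
            class = c("skill_scores", "data.frame"))
}
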