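#' Annual abundance series
#'
#' Container for a yearly breeding-population abundance series (millions of
#' birds), optionally with the survey sampling standard error per year.
#' Years must be strictly increasing; gaps (missing survey years) are allowed
#' and recorded in the `"gaps"` attribute so downstream scoring can skip them.
#'
#' @param years integer vector of calendar years, strictly increasing.
#' @param N positive numeric vector, abundance in millions of birds.
#' @param se optional nonnegative numeric vector, survey SE in millions.
#' @return A data frame of class `abundance_series` with columns `year`, `N`
#'   and (if supplied) `se`.
#' @export
abundance_series <- function(years, N, se = NULL) {
  years <- check_years(years)
  N <- as.numeric(N)
  if (length(N) != length(years)) {
    stop("`N` and `years` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(N)) || any(N <= 0)) {
    bad <- years[!is.finite(N) | N <= 0]
    stop("nonpositive or missing abundance in year(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(year = years, N = N)
  if (!is.null(se)) {
    se <- as.numeric(se)
    if (length(se) != length(years)) {
      stop("`se` and `years` must have equal length", call. = FALSE)
    }
    if (any(se[!is.na(se)] < 0)) stop("negative survey SE", call. = FALSE)
    out$se <- se
  }
  structure(out,
            gaps = setdiff(seq(min(years), max(years)), years),
            class = c("abundance_series", "data.frame"))
}

#' Annual wetland (pond-count) series
#'
#' @param years integer vector of calendar years, strictly increasing.
#' @param W positive numeric vector, ponds in millions.
#' @return A data frame of class `wetland_series` with columns `year`, `W`.
#' @export
wetland_series <- function(years, W) {
  years <- check_years(years)
  W <- as.numeric(W)
  if (length(W) != length(years)) {
    stop("`W` and `years` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(W)) || any(W <= 0)) {
    bad <- years[!is.finite(W) | W <= 0]
    stop("nonpositive or missing pond count in year(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(year = years, W = W),
            class = c("wetland_series", "data.frame"))
}

#' Annual harvest-rate series
#'
#' Harvest rates per age-sex class: adult male (`k_am`), adult female
#' (`k_af`), juvenile male (`k_jm`), juvenile female (`k_jf`). Every rate
#' must lie in \[0, 1).
#'
#' @param years integer vector of calendar years, strictly increasing.
#' @param k_am,k_af,k_jm,k_jf numeric vectors of per-class harvest rates.
#' @return A data frame of class `harvest_series`.
#' @export
harvest_series <- function(years, k_am, k_af, k_jm, k_jf) {
  years <- check_years(years)
  k <- list(k_am = k_am, k_af = k_af, k_jm = k_jm, k_jf = k_jf)
  for (nm in names(k)) {
    v <- as.numeric(k[[nm]])
    if (length(v) != length(years)) {
      stop("`", nm, "` and `years` must have equal length", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0) || any(v >= 1)) {
      stop("harvest rate `", nm, "` outside [0, 1)", call. = FALSE)
    }
    k[[nm]] <- v
  }
  structure(cbind(data.frame(year = years), as.data.frame(k)),
            class = c("harvest_series", "data.frame"))
}

check_years <- function(years) {
  years <- as.integer(years)
  if (length(years) == 0 || any(is.na(years))) {
    stop("years must be non-missing integers", call. = FALSE)
  }
  dup <- unique(years[duplicated(years)])
  if (length(dup)) {
    stop("duplicated year(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly increasing (sort input by year)",
         call. = FALSE)
  }
  years
}

series_columns <- list(
  abundance = c("year", "n_millions", "se_millions"),
  wetland   = c("year", "ponds_millions"),
  harvest   = c("year", "k_am", "k_af", "k_jm", "k_jf")
)

#' Read an annual series from CSV
#'
#' Column conventions: abundance `year,n_millions[,se_millions]`; wetland
#' `year,ponds_millions`; harvest `year,k_am,k_af,k_jm,k_jf`. Rows may be in
#' any order; the returned series is sorted by year. Duplicate years and
#' nonpositive abundances are hard errors naming the offending year.
#'
#' @param path path to a CSV file with a header row.
#' @param kind one of `"abundance"`, `"wetland"`, `"harvest"`.
#' @return An [abundance_series()], [wetland_series()] or [harvest_series()].
#' @export
read_series <- function(path, kind = c("abundance", "wetland", "harvest")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(series_columns[[kind]], "se_millions")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$year), , drop = FALSE]
  switch(kind,
    abundance = abundance_series(df$year, df$n_millions,
                                 se = df[["se_millions"]]),
    wetland   = wetland_series(df$year, df$ponds_millions),
    harvest   = harvest_series(df$year, df$k_am, df$k_af, df$k_jm, df$k_jf)
  )
}

#' Write an annual series to CSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip reproduces every value exactly.
#'
#' @param x a series created by this package.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "abundance_series")) {
    names(df)[names(df) == "N"] <- "n_millions"
    names(df)[names(df) == "se"] <- "se_millions"
  } else if (inherits(x, "wetland_series")) {
    names(df)[names(df) == "W"] <- "ponds_millions"
  } else if (!inherits(x, "harvest_series")) {
    stop("not a recognised series object", call. = FALSE)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Standardize a wetland series to z-scores
#'
#' The wetland covariate enters the growth models standardized to mean 0,
#' sd 1 (sample sd, n-1 denominator). Two conventions are supported:
#'
#' * **fixed baseline** — mean/sd computed once over a stated year window
#'   (or the whole series) and applied to every year, mimicking a
#'   published-constants workflow;
#' * **recursive** (default in the forecasting pipeline) — the z-score for
#'   year *t* uses the mean/sd of years `<= t` only, so no future data leak
#'   into a forecast made at *t*. Years with fewer than two observations of
#'   history, or a degenerate (zero) expanding sd, are returned as `NA`.
#'
#' @param w a [wetland_series()].
#' @param baseline `"recursive"`, `"all"`, or a length-2 year range
#'   `c(first, last)` for a fixed baseline window.
#' @return A data frame of class `standardized_wetlands` with columns
#'   `year`, `W_std`, `mean_t`, `sd_t` (the constants actually used per
#'   year) and attributes `mode`, `baseline_mean`, `baseline_sd` (scalars
#'   for fixed mode).
#' @export
standardize_wetlands <- function(w, baseline = "recursive") {
  stopifnot(inherits(w, "wetland_series"))
  recursive <- identical(baseline, "recursive")
  if (recursive) {
    n <- nrow(w)
    m <- s <- z <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i < 2L) next
      m[i] <- mean(w$W[1:i])
      s[i] <- stats::sd(w$W[1:i])
      if (s[i] > 0) z[i] <- (w$W[i] - m[i]) / s[i] else s[i] <- NA_real_
    }
    out <- data.frame(year = w$year, W_std = z, mean_t = m, sd_t = s)
    return(structure(out, mode = "recursive",
                     baseline_mean = NA_real_, baseline_sd = NA_real_,
                     class = c("standardized_wetlands", "data.frame")))
  }
  if (identical(baseline, "all")) {
    idx <- seq_len(nrow(w))
  } else if (is.numeric(baseline) && length(baseline) == 2) {
    idx <- which(w$year >= baseline[1] & w$year <= baseline[2])
  } else {
    stop("`baseline` must be \"recursive\", \"all\", or a year range",
         call. = FALSE)
  }
  if (length(idx) < 2) {
    stop("baseline window must contain at least 2 years", call. = FALSE)
  }
  mu <- mean(w$W[idx])
  sdv <- stats::sd(w$W[idx])
  if (sdv == 0) {
    stop("degenerate standardization: baseline sd is zero", call. = FALSE)
  }
  out <- data.frame(year = w$year, W_std = (w$W - mu) / sdv,
                    mean_t = mu, sd_t = sdv)
  structure(out, mode = "fixed", baseline_mean = mu, baseline_sd = sdv,
            class = c("standardized_wetlands", "data.frame"))
}
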