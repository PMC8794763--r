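# Shared fixture builders. Everything is generated in code; no stored data.

fix_abundance <- function(years = 2000:2002, N = c(5.0, 6.2, 7.1),
                          se = NULL) {
  abundance_series(years, N, se = se)
}

fix_wetlands <- function(years = 2000:2002, W = c(2, 4, 6)) {
  wetland_series(years, W)
}

# A forecast table built directly from normal records, for scoring and
# weight-updating tests where forecasts are specified rather than modelled.
fix_table <- function(model_ids, years, means, sds, observed) {
  rows <- list()
  for (j in seq_along(model_ids)) {
    for (i in seq_along(years)) {
      rec <- forecast_record(model_ids[j], years[i], family = "normal",
                             par1 = means[[j]][i], par2 = sds[[j]][i])
      rec$observed <- observed[i]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  structure(do.call(rbind, rows),
            class = c("forecast_table", "data.frame"))
}

# Normal sd such that the density at the record's own mean equals `dens`.
sd_for_peak_density <- function(dens) 1 / (dens * sqrt(2 * pi))

# Deterministic demo scenario used by several pipeline tests.
demo_scenario <- function(generator = "SaRw", n_years = 40, seed = 7,
                          ...) {
  scenario_spec(generator = generator, n_years = n_years, seed = seed, ...)
}

write_demo_config <- function(path, overrides = list()) {
  cfg <- list(seed = 7, simulate = list(generator = "persistence",
                                        n_years = 30))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  yaml::write_yaml(cfg, path)
  path
}
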