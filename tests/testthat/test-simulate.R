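test_that("simulation is deterministic under a fixed seed", {
  spec <- demo_scenario(seed = 18)
  b1 <- simulate_population(spec)
  b2 <- simulate_population(spec)
  expect_identical(b1$abundance, b2$abundance)
  expect_identical(b1$wetland, b2$wetland)
  expect_identical(b1$harvest, b2$harvest)
  # and the emitted CSVs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(b1, d1); write_scenario(b2, d2)
  for (f in c("abundance.csv", "wetland.csv", "harvest.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("wetland AR(1) has the specified structure", {
  # zero innovation sd: constant at the mean
  s0 <- demo_scenario(seed = 19, wetland = list(mean = 4, phi = 0.7,
                                                sd = 0))
  expect_true(all(simulate_wetlands(s0)$W == 4))

  # phi = 0: i.i.d. lognormal, lag-1 autocorrelation near zero
  s1 <- scenario_spec(n_years = 2000, seed = 20,
                      wetland = list(mean = 4, phi = 0, sd = 0.25))
  w <- simulate_wetlands(s1)
  ac <- cor(log(w$W[-1]), log(w$W[-2000]))
  expect_lt(abs(ac), 2 / sqrt(2000))
  # log-scale moments near specification (phi = 0: sd = innovation sd)
  expect_lt(abs(mean(log(w$W)) - log(4)), 3 * 0.25 / sqrt(2000))
  expect_lt(abs(sd(log(w$W)) - 0.25), 3 * 0.25 / sqrt(2 * 2000))

  expect_error(scenario_spec(wetland = list(mean = 4, phi = 1.2,
                                            sd = 0.2)),
               "phi")
})

test_that("process innovations have the specified moments", {
  spec <- scenario_spec(generator = "persistence", n_years = 2000,
                        process_sd = 0.05,
                        obs = list(type = "lognormal", cv = 0), seed = 21)
  b <- simulate_population(spec)
  inn <- diff(log(b$truth$N))
  expect_lt(abs(mean(inn)), 3 * 0.05 / sqrt(length(inn)))
  expect_lt(abs(sd(inn) - 0.05), 3 * 0.05 / sqrt(2 * length(inn)))
})

test_that("noise-free persistence generator gives a constant series", {
  spec <- scenario_spec(generator = "persistence", process_sd = 0,
                        obs = list(type = "lognormal", cv = 0), seed = 22)
  b <- simulate_population(spec)
  expect_true(all(b$abundance$N == b$abundance$N[1]))
})

test_that("noise-free wetland generator reproduces beta * W_std exactly", {
  spec <- scenario_spec(generator = "wetland", beta = 0.1, process_sd = 0,
                        obs = list(type = "lognormal", cv = 0), seed = 23)
  d <- withr::local_tempdir()
  write_scenario(simulate_population(spec), d)
  # recompute from the emitted files alone
  a <- read_series(file.path(d, "abundance.csv"), "abundance")
  w <- read_series(file.path(d, "wetland.csv"), "wetland")
  z <- standardize_wetlands(w, baseline = "all")
  growth <- log(a$N[-1] / a$N[-nrow(a)])
  expect_equal(growth, 0.1 * z$W_std[-nrow(z)], tolerance = 1e-12)
})

test_that("noise-free AHM generator equals a hand-rolled iteration", {
  spec <- scenario_spec(generator = "SaRw", process_sd = 0,
                        obs = list(type = "lognormal", cv = 0),
                        n_years = 20, seed = 24)
  b <- simulate_population(spec)
  p <- spec$ahm
  # independent loop oracle written from the model definition
  N <- numeric(20); N[1] <- spec$N0
  for (t in 1:19) {
    h <- b$harvest[t, ]
    K <- c(h$k_am, h$k_af, h$k_jm, h$k_jf) / (1 - p$survival$crippling_loss)
    S <- p$survival$s0[c("am", "af", "jm", "jf")] * (1 - K)
    R <- max(0, p$repro$weak$a0 + p$repro$weak$a1 * N[t] +
               p$repro$weak$a2 * b$w_std$W_std[t])
    N[t + 1] <- N[t] * (p$balance$m * S[["am"]] +
                          (1 - p$balance$m) *
                            (S[["af"]] + R * (S[["jf"]] +
                                                S[["jm"]] *
                                                  p$balance$phi_ratio)))
  }
  expect_equal(b$truth$N, N, tolerance = 1e-12)
})

test_that("unstable parameterizations fail loudly with the year", {
  p <- default_ahm_params()
  p$repro$weak$a0 <- 8   # absurd fecundity without density dependence:
  p$repro$weak$a1 <- 0   # sustained ~5x annual growth, unbounded
  spec <- scenario_spec(generator = "SaRw", ahm = p, n_years = 60,
                        seed = 25)
  expect_error(simulate_population(spec), "19[0-9]{2}")
})
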