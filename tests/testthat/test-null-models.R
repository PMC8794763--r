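test_that("persistence forecast equals the last observation exactly", {
  h <- fix_abundance(N = c(5.0, 6.2, 7.1))
  f <- persistence_forecast(h, target_year = 2003)
  expect_identical(f$mean, 7.1)
  expect_equal(f$sd, sd(c(1.2, 0.9)), tolerance = 1e-12)
  expect_identical(f$family, "normal")

  const <- fix_abundance(N = c(6, 6, 6))
  fc <- persistence_forecast(const)
  expect_identical(fc$mean, 6)
  expect_identical(fc$sd, 0)

  two <- fix_abundance(years = 2000:2001, N = c(5, 6.5))
  expect_equal(persistence_forecast(two)$sd, 1.5)

  expect_error(persistence_forecast(fix_abundance(2000, 5)), "2 years")

  # bit-identical mean for arbitrary histories
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    hh <- abundance_series(seq_len(n) + 1980, runif(n, 3, 12))
    expect_identical(persistence_forecast(hh)$mean, hh$N[n])
  }
})

test_that("wetland-model fit recovers a noise-free signal", {
  set.seed(4)
  n <- 30
  w <- wetland_series(1980 + 0:n, exp(rnorm(n + 1, 1.3, 0.3)))
  z <- standardize_wetlands(w, baseline = "all")
  N <- numeric(n + 1); N[1] <- 8
  for (t in 1:n) N[t + 1] <- N[t] * exp(0.1 * z$W_std[t])
  a <- abundance_series(w$year, N)
  vague <- wetland_prior(beta_scale = 1e6, a = 1e-4, b = 1e-4)
  post <- fit_wetland_model(a, z, vague)
  # oracle: least squares through the origin (vague prior limit)
  g <- growth_observations(a, z)
  beta_ols <- sum(g$x * g$y) / sum(g$x^2)
  expect_equal(post$beta_mean, beta_ols, tolerance = 1e-6)
  expect_equal(post$beta_mean, 0.1, tolerance = 1e-6)
  expect_lt(post$sigma2_mean, 1e-4)
  expect_equal(post$n_obs, n)
})

test_that("zero-signal data give a zero posterior mean exactly", {
  w <- wetland_series(1980:1989, c(2, 5, 3, 6, 4, 7, 2.5, 5.5, 3.5, 6.5))
  z <- standardize_wetlands(w, baseline = "all")
  a <- abundance_series(1980:1989, rep(7, 10))  # all growth rates zero
  post <- fit_wetland_model(a, z)
  expect_identical(post$beta_mean, 0)
  expect_error(fit_wetland_model(a[1:3, ], z), "3 growth observations")
})

test_that("sequential conjugate updates equal the batch fit", {
  set.seed(5)
  x <- rnorm(40)
  y <- 0.1 * x + rnorm(40, 0, 0.05)
  batch <- ahmnull:::update_nig(wetland_prior(), x, y)
  seq_post <- wetland_prior()
  for (i in seq_along(x)) {
    seq_post <- update_wetland_model(seq_post, x[i], y[i])
  }
  for (fld in c("beta_mean", "beta_scale", "a", "b")) {
    expect_equal(seq_post[[fld]], batch[[fld]], tolerance = 1e-10)
  }
  expect_identical(seq_post$n_obs, 40L)
})

test_that("beta recovery on a simulated wetland-growth series", {
  spec <- scenario_spec(generator = "wetland", beta = 0.1,
                        process_sd = 0.05, n_years = 100,
                        obs = list(type = "lognormal", cv = 0), seed = 31)
  b <- simulate_population(spec)
  post <- fit_wetland_model(b$abundance, b$w_std)
  expect_lt(abs(post$beta_mean - 0.1), 2 * post$beta_sd)
})

test_that("with beta pinned at 0 the wetland model reduces to persistence", {
  set.seed(6)
  n <- 25
  w <- wetland_series(1980 + 0:n, exp(rnorm(n + 1, 1.4, 0.3)))
  z <- standardize_wetlands(w, baseline = "all")
  N <- 8 * exp(cumsum(c(0, rnorm(n, 0, 0.05))))
  a <- abundance_series(w$year, N)
  prior0 <- wetland_prior(fixed_beta = 0)
  for (t in 5:n) {
    hist_a <- a[1:t, ]
    class(hist_a) <- class(a)
    post <- fit_wetland_model(hist_a, z, prior0)
    f <- wetland_forecast(post, hist_a$N[t], z$W_std[t])
    pers <- persistence_forecast(hist_a)
    # predictive median on the abundance scale = exp(location)
    expect_equal(exp(f$par1), pers$mean, tolerance = 1e-12)
  }
})

test_that("near-deterministic posterior forecasts N_t * exp(beta * W)", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  y <- 0.1 * x  # no residual noise
  post <- ahmnull:::update_nig(wetland_prior(beta_scale = 1e6, a = 1e-3,
                                             b = 1e-6), x, y)
  f <- wetland_forecast(post, 8, 1, target_year = 2001)
  expect_equal(f$mean, 8 * exp(0.1), tolerance = 1e-3)
  expect_lt(f$sd, 0.01)
})

test_that("t-predictive moments match a posterior-predictive MC oracle", {
  set.seed(8)
  x <- rnorm(30)
  y <- 0.1 * x + rnorm(30, 0, 0.06)
  post <- ahmnull:::update_nig(wetland_prior(), x, y)
  f <- wetland_forecast(post, 8, 0.7)
  expect_identical(f$family, "student-t")
  draws <- exp(f$par1 + f$par2 * rt(1e5, df = f$par3))
  se_mean <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - f$mean), 3 * se_mean)
  v <- var(draws)
  se_sd <- sqrt((mean((draws - mean(draws))^4) - v^2) / length(draws)) /
    (2 * sqrt(v))
  expect_lt(abs(sd(draws) - f$sd), 3 * se_sd)
})
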