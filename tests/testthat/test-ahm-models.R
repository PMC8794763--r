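test_that("kill rate inflates harvest rate for crippling loss", {
  expect_equal(kill_rate(0.1, 0), 0.1)
  expect_equal(kill_rate(0.1, 0.2), 0.125)
  expect_error(kill_rate(0.9, 0.2), "kill rate")
})

test_that("survival hypotheses have the stated forms and ordering", {
  expect_equal(survival_additive(0.9, 0), 0.9)
  expect_equal(survival_additive(0.9, 0.2), 0.72)
  expect_equal(survival_additive(1.0, 0.5), 0.5)
  expect_equal(survival_compensatory(0.9, 0.05), 0.9)  # below C = 0.1
  expect_equal(survival_compensatory(0.9, 0.3), 0.7)   # 1 - K above C
  expect_equal(survival_compensatory(0.9, 0.1), 0.9)   # continuous at C

  K <- seq(0, 0.99, by = 0.01)
  for (s0 in c(0.6, 0.85, 0.95)) {
    add <- survival_additive(s0, K)
    comp <- survival_compensatory(s0, K)
    expect_true(all(comp >= add))
    expect_identical(which(comp == add), which(K == 0))
    # additive: linear, strictly decreasing
    expect_equal(diff(add), rep(-s0 * 0.01, length(K) - 1))
    # compensatory: flat below the threshold C = 1 - s0
    below <- K <= 1 - s0
    expect_true(all(comp[below] == s0))
  }
})

test_that("reproduction is linear with zero truncation", {
  expect_equal(reproduction_rate(list(a0 = .8, a1 = 0, a2 = 0), 7, 1), 0.8)
  expect_equal(reproduction_rate(list(a0 = .8, a1 = -.1, a2 = .2), 7, 1),
               0.3)
  expect_equal(reproduction_rate(list(a0 = .1, a1 = -.1, a2 = 0), 7, 0), 0)
})

test_that("balance equation matches an independent hand evaluation", {
  bal <- list(gamma_S = 1, gamma_R = 1, m = 0.55, phi_ratio = 1.2)
  s <- c(am = 0.85, af = 0.70, jm = 0.65, jf = 0.60)
  # independently evaluated expression
  expected <- 8 * (0.55 * 0.85 +
                     0.45 * (0.70 + 0.9 * (0.60 + 0.65 * 1.2)))
  expect_equal(balance_step(8, s, 0.9, bal), expected, tolerance = 1e-12)

  # pure survival, no recruits: N unchanged
  ones <- c(am = 1, af = 1, jm = 1, jf = 1)
  expect_equal(balance_step(7.3, ones, 0, bal), 7.3)
  # uniform adult survival
  s2 <- c(am = .9, af = .9, jm = 0, jf = 0)
  bal2 <- list(gamma_S = 1, gamma_R = 1, m = 0.5, phi_ratio = 1)
  expect_equal(balance_step(6, s2, 0, bal2), 5.4)
})

test_that("balance map is degree-1 homogeneous without density dependence", {
  p <- default_ahm_params()
  p$repro$weak$a1 <- 0
  h <- c(am = .1, af = .07, jm = .15, jf = .1)
  surv <- class_survival("additive", h, p$survival)
  step <- function(N) {
    balance_step(N, surv, reproduction_rate(p$repro$weak, N, 0.5),
                 p$balance)
  }
  for (N in c(2, 5, 9)) expect_equal(step(2 * N), 2 * step(N))
})

test_that("density dependence yields one attracting fixed point", {
  p <- default_ahm_params()
  h <- c(am = .1, af = .07, jm = .15, jf = .1)
  surv <- class_survival("additive", h, p$survival)
  step <- function(N) {
    balance_step(N, surv, reproduction_rate(p$repro$strong, N, 0), p$balance)
  }
  grid <- seq(0.5, 30, by = 0.05)
  signs <- sign(vapply(grid, step, numeric(1)) - grid)
  expect_equal(sum(diff(signs) != 0), 1)  # exactly one crossing
  nstar <- uniroot(function(N) step(N) - N,
                   lower = 0.5, upper = 30, tol = 1e-12)$root
  for (N0 in c(nstar / 2, nstar * 2)) {
    traj <- Reduce(function(N, .) step(N), 1:200, accumulate = TRUE,
                   init = N0)
    gaps <- abs(traj - nstar)
    expect_true(all(diff(gaps) <= 1e-9))
    expect_lt(gaps[length(gaps)], 1e-6)
  }
})

test_that("AHM forecasts wrap the balance step in a lognormal", {
  p <- default_ahm_params()
  h <- c(am = .1, af = .07, jm = .15, jf = .1)
  # noise-free limit: degenerate record at the balance output
  p0 <- p; p0$balance$process_sd <- 0
  f0 <- ahm_forecast("SaRw", 8, 0.5, h, p0, target_year = 2001)
  surv <- class_survival("additive", h, p$survival)
  med <- balance_step(8, surv, reproduction_rate(p$repro$weak, 8, 0.5),
                      p$balance)
  expect_equal(f0$sd, 0)
  expect_equal(f0$mean, med, tolerance = 1e-12)

  # compensatory >= additive forecast mean when K is below every threshold
  f_add <- ahm_forecast("SaRw", 8, 0.5, h, p, target_year = 2001)
  f_comp <- ahm_forecast("ScRw", 8, 0.5, h, p, target_year = 2001)
  expect_gte(f_comp$mean, f_add$mean)

  expect_error(ahm_forecast("SxRw", 8, 0.5, h, p), "unknown AHM model")
})

test_that("lognormal forecast moments match a Monte-Carlo oracle", {
  p <- default_ahm_params()  # process_sd = 0.05
  h <- c(am = .1, af = .07, jm = .15, jf = .1)
  f <- ahm_forecast("SaRw", 8, 0.5, h, p, target_year = 2001)
  set.seed(99)
  draws <- exp(rnorm(1e5, f$par1, f$par2))
  se_mean <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - f$mean), 3 * se_mean)
  v <- var(draws)
  se_sd <- sqrt((mean((draws - mean(draws))^4) - v^2) / length(draws)) /
    (2 * sqrt(v))
  expect_lt(abs(sd(draws) - f$sd), 3 * se_sd)
})
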