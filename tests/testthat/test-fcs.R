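test_that("the autocorrelation model has its closed-form values and limits", {
  p0 <- fcs_params(N = 1, tau_D = 1e-3, s = 0.175)
  expect_equal(fcs_model_g(p0, 1e-12), 1.0, tolerance = 1e-6)
  p1 <- fcs_params(N = 2, tau_D = 1e-3, s = 0.175,
                   kinetic = list(c(A = 0.3, tau_R = 1e-6)))
  expect_equal(fcs_model_g(p1, 0), 0.65)
  # at lag = tau_D the pure-diffusion curve is 0.5 / sqrt(1 + s^2)
  expect_equal(fcs_model_g(p0, 1e-3), 0.5 / sqrt(1 + 0.175^2))
  expect_equal(round(fcs_model_g(p0, 1e-3), 4), 0.4925)
  # strictly decreasing, vanishing at long lags
  lags <- 10^seq(-7, 1, length.out = 200)
  g <- fcs_model_g(p1, lags)
  expect_true(all(diff(g) < 0))
  expect_lt(fcs_model_g(p1, 10), 1e-3)
  expect_error(fcs_params(N = -1, tau_D = 1e-3), "N must be positive")
  expect_error(fcs_params(N = 1, tau_D = 0), "tau_D")
  expect_error(fcs_params(N = 1, tau_D = 1e-3, s = 1.5), "s must")
})

test_that("curve averaging computes pointwise means and sample variances", {
  lags <- c(1e-6, 1e-5, 1e-4)
  c1 <- correlation_curve(lags, c(0.5, 0.4, 0.2))
  expect_identical(average_curves(list(c1, c1))$variance, c(0, 0, 0))
  c2 <- correlation_curve(lags, -c(0.5, 0.4, 0.2))
  avg <- average_curves(list(c1, c2))
  expect_equal(avg$g, c(0, 0, 0))
  expect_equal(avg$variance, 2 * c(0.5, 0.4, 0.2)^2)  # two-point variance
  expect_equal(avg$n_acquisitions, 2L)
  c3 <- correlation_curve(lags * 2, c(0.5, 0.4, 0.2))
  expect_error(average_curves(list(c1, c3)), "identical lag grid")
})

test_that("averaged noisy replicates track the generating model", {
  p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                  kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
  curves <- make_noisy_curves(p, seed = 101, n_replicates = 10)
  avg <- average_curves(curves)
  # z-scores against the generator's true per-lag noise SD
  duration <- 30
  sd_true <- 0.02 * (fcs_model_g(p, avg$lags) + sqrt(avg$lags / duration))
  z <- (avg$g - fcs_model_g(p, avg$lags)) / (sd_true / sqrt(10))
  expect_lt(max(abs(z)), 4)          # no gross outlier across 140 lags
  expect_gt(mean(abs(z) < 3), 0.97)  # and the bulk sits within 3 SE
})

test_that("noiseless curves are recovered to numerical precision", {
  p <- fcs_params(N = 1.7, tau_D = 3e-4, s = 0.175,
                  kinetic = list(c(A = 0.45, tau_R = 2e-6)))
  avg <- suppressWarnings(
    average_curves(simulate_fcs_curve(p, noise_level = 0, n_replicates = 2)))
  fit <- suppressWarnings(fit_fcs_curve(avg, 1, s_fixed = 0.175))
  k <- fit$params$kinetic[[1]]
  expect_lt(abs(fit$params$N / 1.7 - 1), 1e-3)
  expect_lt(abs(fit$params$tau_D / 3e-4 - 1), 1e-3)
  expect_lt(abs(k[["A"]] / 0.45 - 1), 1e-3)
  expect_lt(abs(k[["tau_R"]] / 2e-6 - 1), 1e-3)
  expect_true(fit$converged)
  expect_gt(fit$r_squared, 0.999999)
  expect_equal(length(fit$residuals), length(avg$lags))
})

test_that("uniform variances give the same fit as unit weights", {
  p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                  kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
  curves <- make_noisy_curves(p, seed = 7, n_replicates = 6)
  avg <- average_curves(curves)
  unif <- correlation_curve(avg$lags, avg$g,
                            rep(2.5e-5, length(avg$lags)),
                            avg$n_acquisitions)
  unwt <- correlation_curve(avg$lags, avg$g,
                            rep(0, length(avg$lags)), avg$n_acquisitions)
  f1 <- fit_fcs_curve(unif, 1, s_fixed = 0.175)
  f2 <- suppressWarnings(fit_fcs_curve(unwt, 1, s_fixed = 0.175))
  expect_equal(f1$params$kinetic[[1]][["tau_R"]],
               f2$params$kinetic[[1]][["tau_R"]], tolerance = 1e-6)
  expect_equal(f1$params$N, f2$params$N, tolerance = 1e-6)
})

test_that("seeded noisy fits recover the relaxation time within 10%", {
  p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                  kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
  for (seed in c(21, 22, 23)) {
    avg <- average_curves(make_noisy_curves(p, seed = seed))
    fit <- fit_fcs_curve(avg, 1, s_fixed = 0.175)
    expect_lt(abs(fit$params$kinetic[[1]][["tau_R"]] / 1.2e-6 - 1), 0.10)
  }
})

test_that("a second kinetic component neither degrades R^2 nor moves tau_R", {
  p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                  kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
  avg <- average_curves(make_noisy_curves(p, seed = 31))
  f1 <- fit_fcs_curve(avg, 1, s_fixed = 0.175)
  f2 <- fit_fcs_curve(avg, 2, s_fixed = 0.175)
  expect_gte(f2$r_squared + 1e-12, f1$r_squared)
  expect_lt(f2$r_squared - f1$r_squared, 0.001)
  # dominant component of the 2-term fit agrees with the 1-term tau_R
  k2 <- f2$params$kinetic
  dominant <- k2[[which.max(vapply(k2, `[[`, numeric(1), "A"))]]
  tau1 <- f1$params$kinetic[[1]][["tau_R"]]
  expect_lt(abs(dominant[["tau_R"]] / tau1 - 1), 0.25)
})

test_that("free-dye calibration recovers the observation-volume ratio", {
  for (s_true in c(0.175, 0.2)) {
    p <- fcs_params(N = 1.5, tau_D = 5e-5, s = s_true)
    avg <- average_curves(make_noisy_curves(p, seed = 41, noise_level = 0.01))
    cal <- calibrate_s(avg)
    expect_true(cal$ok)
    expect_lt(abs(cal$s - s_true), 0.005)
  }
})

test_that("calibration flags a two-species sample as a poor fit", {
  lags <- 10^seq(-7, -1, length.out = 140)
  fast <- fcs_model_g(fcs_params(N = 2, tau_D = 3e-5, s = 0.175), lags)
  slow <- fcs_model_g(fcs_params(N = 2, tau_D = 3e-3, s = 0.175), lags)
  mix <- fast + slow
  set.seed(5)
  curves <- lapply(1:10, function(i) {
    correlation_curve(lags, mix + stats::rnorm(length(lags), 0, 0.002))
  })
  expect_warning(cal <- calibrate_s(average_curves(curves)), "poor")
  expect_false(cal$ok)
})
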