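test_that("fast-path curve simulation is exact at zero noise and seeded", {
  p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
                  kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
  clean <- simulate_fcs_curve(p, noise_level = 0, n_replicates = 3)
  for (cv in clean) {
    expect_equal(cv$g, fcs_model_g(p, cv$lags))
  }
  a <- simulate_fcs_curve(p, seed = 81)
  b <- simulate_fcs_curve(p, seed = 81)
  expect_identical(a, b)
  c2 <- simulate_fcs_curve(p, seed = 82)
  expect_false(identical(a, c2))
  # replicate scatter produces positive variance at every lag
  avg <- average_curves(simulate_fcs_curve(p, seed = 83, n_replicates = 12))
  expect_true(all(avg$variance > 0))
})

test_that("photon traces are seeded and obey closed-form count rates", {
  p <- fcs_sim_params(N = 2, tau_D = 1e-4, duration = 0.1, seed = 84,
                      box_xy_factor = 6, box_z_factor = 6)
  t1 <- simulate_photon_trace(p)
  t2 <- simulate_photon_trace(p)
  expect_identical(t1$channel_1, t2$channel_1)
  expect_identical(t1$channel_2, t2$channel_2)
  total <- t1$channel_1 + t1$channel_2
  # block-wise standard error of the mean rate
  blocks <- colSums(matrix(total, ncol = 20))
  rate <- sum(total) / p$duration
  se <- stats::sd(blocks / (p$duration / 20)) / sqrt(20)
  expect_lt(abs(rate - expected_count_rate(p)), 3 * se)
})

test_that("zero brightness gives a pure Poisson background trace", {
  p <- fcs_sim_params(N = 2, tau_D = 1e-4, brightness = 0, background = 1e5,
                      k_to_dark = 0, k_to_bright = 0,
                      duration = 1, bin_width = 1e-4, seed = 85,
                      box_xy_factor = 6, box_z_factor = 6)
  tr <- simulate_photon_trace(p)
  total <- tr$channel_1 + tr$channel_2
  lambda <- p$background * p$bin_width
  expect_equal(mean(total), lambda, tolerance = 0.05)
  expect_equal(stats::var(total), lambda, tolerance = 0.1)
  # background photons carry no correlation (per-lag estimator SE ~ 2e-3)
  cc <- multi_tau_correlate(tr, n_levels = 4)
  expect_lt(max(abs(cc$g)), 0.01)
})

test_that("suppressing the dark state removes the kinetic component", {
  base <- list(N = 2, tau_D = 1e-4, s = 0.175, brightness = 5e5,
               background = 2e3, duration = 0.5, bin_width = 5e-7,
               box_xy_factor = 6, box_z_factor = 6)
  p <- do.call(fcs_sim_params, c(base, list(k_to_dark = 0,
                                            k_to_bright = 1.4e5)))
  curves <- lapply(1:4, function(i) {
    p$seed <- 860 + i
    multi_tau_correlate(simulate_photon_trace(p))
  })
  avg <- average_curves(curves)
  f1 <- fit_fcs_curve(avg, 1, s_fixed = 0.175)
  f0 <- fit_fcs_curve(avg, 0, s_fixed = 0.175)
  # the extra kinetic term buys essentially nothing ...
  expect_lt(f1$r_squared - f0$r_squared, 0.005)
  # ... and whatever it absorbed decays by < 5% across the microsecond
  # window where a real quenching component would fall off
  k <- f1$params$kinetic[[1]]
  kin_decay <- (1 + k[["A"]] * exp(-avg$lags[1] / k[["tau_R"]])) /
    (1 + k[["A"]] * exp(-avg$lags[16] / k[["tau_R"]]))
  expect_lt(kin_decay - 1, 0.05)
})

test_that("multi-tau equals direct correlation to 1e-10 on a 1e4-bin trace", {
  set.seed(87)
  n <- 1e4
  ch1 <- stats::rpois(n, 3) + stats::rbinom(n, 1, 0.2) * stats::rpois(n, 5)
  ch2 <- stats::rpois(n, 3)
  mt <- multi_tau_correlate(channel_1 = ch1, channel_2 = ch2,
                            bin_width = 1e-6, n_levels = 6)
  oracle <- brute_force_multitau(ch1, ch2, 1e-6, n_levels = 6)
  expect_equal(mt$lags, oracle$lags)
  expect_lt(max(abs(mt$g - oracle$g)), 1e-10)
})

test_that("degenerate traces correlate to zero", {
  const <- rep(5, 5000)
  cc <- multi_tau_correlate(channel_1 = const, channel_2 = const,
                            bin_width = 1e-6, n_levels = 3)
  expect_equal(cc$g, rep(0, length(cc$g)))
  # independent white noise: correlation consistent with zero
  set.seed(88)
  w <- multi_tau_correlate(channel_1 = stats::rpois(2e4, 5),
                           channel_2 = stats::rpois(2e4, 5),
                           bin_width = 1e-6, n_levels = 4)
  expect_lt(max(abs(w$g)), 0.006)  # ~4 SE of the estimator at these sizes
  # over-long ladder on a short trace warns and truncates
  expect_warning(
    short <- multi_tau_correlate(channel_1 = stats::rpois(200, 5),
                                 channel_2 = stats::rpois(200, 5),
                                 bin_width = 1e-6, n_levels = 12),
    "truncated")
  expect_lt(length(short$lags), 12 * 16)
})

test_that("burst streams are seeded and recover the true efficiency", {
  p <- burst_sim_params(0.84, seed = 89)
  b1 <- simulate_bursts(p)
  b2 <- simulate_bursts(p)
  expect_identical(b1$i_donor, b2$i_donor)
  for (et_true in c(0.2, 0.5, 0.84)) {
    bs <- simulate_bursts(burst_sim_params(et_true, n_events = 3000,
                                           seed = round(1000 * et_true)))
    st <- attr(bs, "buffer_stats")
    kept <- apply_threshold(bs, select_threshold(st$mean, st$sd))
    et <- compute_eteff(kept$i_donor, kept$i_acceptor)
    fit <- fit_double_gaussian(eteff_histogram(et))
    expect_lt(abs(fit$mean_et - et_true), 0.01,
              label = sprintf("true ET %.2f", et_true))
  }
})

test_that("an all-donor-only stream has no FRET peak", {
  bs <- simulate_bursts(burst_sim_params(0.8, n_events = 3000,
                                         donor_only_fraction = 1, seed = 90))
  et <- compute_eteff(bs$i_donor, bs$i_acceptor)
  h <- eteff_histogram(et)
  # no mass in the FRET region
  expect_lt(sum(h$counts[h$mids > 0.4]), 0.01 * h$n_events)
})
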