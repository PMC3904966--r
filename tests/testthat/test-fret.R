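test_that("threshold selection and application separate bursts from buffer", {
  expect_equal(select_threshold(2, 1, k = 5), 7)
  expect_error(select_threshold(2, 1, k = 0), "positive")
  # buffer-only stream: nearly all events rejected at the default k
  set.seed(61)
  buf <- burst_set(stats::rpois(5000, 1), stats::rpois(5000, 1))
  kept <- apply_threshold(buf, select_threshold(2, sqrt(2)))
  expect_gte(attr(kept, "n_rejected") / 5000, 0.99)
  # bright bursts: nearly all retained
  bright <- simulate_bursts(burst_sim_params(0.5, n_events = 2000, seed = 62))
  bs <- attr(bright, "buffer_stats")
  kept2 <- apply_threshold(bright, select_threshold(bs$mean, bs$sd))
  expect_gte(nrow(kept2) / 2000, 0.95)
})

test_that("corrected efficiency algebra matches hand substitution", {
  expect_equal(compute_eteff(100, 160, corrections(0.6, 1.2)),
               100 / 220, ignore_attr = TRUE)
  # acceptor signal entirely bleed-through -> ET = 0
  expect_equal(compute_eteff(50, 30, corrections(0.6, 1.2)), 0,
               ignore_attr = TRUE)
  expect_equal(compute_eteff(0, 80), 1, ignore_attr = TRUE)
  # invariant under joint scaling of both channels
  set.seed(63)
  id <- stats::rpois(100, 40) + 1
  ia <- stats::rpois(100, 60)
  expect_equal(compute_eteff(id, ia), compute_eteff(7 * id, 7 * ia),
               ignore_attr = TRUE)
  # non-positive corrected denominator -> NA, counted
  et <- compute_eteff(c(100, 10), c(160, 0), corrections(2, 1))
  expect_true(is.na(et[2]))
  expect_equal(attr(et, "n_excluded"), 1)
})

test_that("histograms conserve accepted events", {
  set.seed(64)
  et <- stats::rnorm(3000, 0.8, 0.08)
  h <- eteff_histogram(et)
  expect_equal(sum(h$counts), h$n_events)
  expect_equal(length(h$counts), 70)
  expect_equal(range(h$edges), c(-0.2, 1.2))
})

test_that("double-Gaussian fit recovers exact functional-form histograms", {
  h0 <- eteff_histogram(numeric(0))
  x <- h0$mids
  truth <- list(zero = c(A = 300, w = 0.12, xc = 0.01),
                data = c(A = 900, w = 0.18, xc = 0.82))
  y <- 300 / (0.12 * sqrt(pi / 2)) * exp(-2 * (x - 0.01)^2 / 0.12^2) +
    900 / (0.18 * sqrt(pi / 2)) * exp(-2 * (x - 0.82)^2 / 0.18^2)
  h <- h0
  h$counts <- y
  h$n_events <- round(sum(y))
  fit <- fit_double_gaussian(h)
  expect_false(fit$flagged)
  dpk <- fit$peaks[fit$peaks$role == "data", ]
  zpk <- fit$peaks[fit$peaks$role == "zero", ]
  expect_lt(abs(dpk$center / 0.82 - 1), 0.01)
  expect_lt(abs(dpk$area / 900 - 1), 0.01)
  expect_lt(abs(dpk$width / 0.18 - 1), 0.01)
  expect_lt(abs(zpk$center - 0.01), 0.01 * 0.12 / 0.01)  # center near 0.01
  expect_lt(abs(zpk$area / 300 - 1), 0.01)
})

test_that("sampled two-population histograms yield the data-peak center", {
  set.seed(65)
  et <- c(stats::rnorm(900, 0.02, 0.06), stats::rnorm(2100, 0.84, 0.09))
  fit <- fit_double_gaussian(eteff_histogram(et))
  expect_lt(abs(fit$mean_et - 0.84), 0.01)
  # initialization order does not change peak assignment
  fit_swapped <- fit_double_gaussian(eteff_histogram(et),
                                     init = list(zero_center = 0.84,
                                                 data_center = 0.02))
  expect_equal(fit_swapped$mean_et, fit$mean_et, tolerance = 1e-4)
})

test_that("a single-peak histogram is handled with a near-empty zero peak", {
  set.seed(66)
  et <- stats::rnorm(2500, 0.5, 0.08)
  fit <- fit_double_gaussian(eteff_histogram(et))
  dpk <- fit$peaks[fit$peaks$role == "data", ]
  zpk <- fit$peaks[fit$peaks$role == "zero", ]
  expect_lt(abs(dpk$center - 0.5), 0.01)
  expect_lt(zpk$area, 0.02 * dpk$area)
})

test_that("donor-only populations center at zero with correct beta", {
  bs <- simulate_bursts(burst_sim_params(0.84, n_events = 4000,
                                         donor_only_fraction = 1, seed = 67))
  et <- compute_eteff(bs$i_donor, bs$i_acceptor)
  fit <- fit_double_gaussian(eteff_histogram(et),
                             init = list(zero_center = 0, data_center = 0.8))
  zpk <- fit$peaks[fit$peaks$role == "zero", ]
  expect_lt(abs(zpk$center), 0.02)
  # essentially no FRET-peak mass
  dpk <- fit$peaks[fit$peaks$role == "data", ]
  expect_lt(dpk$area, 0.05 * zpk$area)
})

test_that("repeat summaries follow the reporting convention", {
  r <- mean_eteff_over_repeats(c(0.84, 0.84, 0.84))
  expect_equal(r$mean, 0.84)
  expect_equal(r$sd, 0)
  r2 <- mean_eteff_over_repeats(c(0.83, 0.84, 0.85, 0.84))
  expect_equal(r2$mean, 0.84)
  expect_equal(r2$sd, 0.008, tolerance = 0.03)
  expect_equal(r2$mean_2dp, 0.84)
  expect_warning(mean_eteff_over_repeats(c(0.8, 0.9)), "fewer than 3")
})
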