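#' Simulate noisy correlation curves (fast path)
#'
#' Evaluates the FCS model on a quasi-logarithmic lag grid and adds
#' independent Gaussian noise with per-lag SD
#' `noise_level * (g + 1 / sqrt(n_eff))`, where `n_eff = duration / lag` is
#' the number of independent lag windows in one acquisition — so long lags
#' are noisier relative to their amplitude, as in measured curves. This is
#' the quick generator for fit testing; [simulate_photon_trace()] plus
#' [multi_tau_correlate()] is the physical route.
#'
#' @param params An [fcs_params()] object (the generating truth).
#' @param noise_level Relative noise scale (default 0.02; 0 gives exact
#'   model curves).
#' @param n_replicates Number of replicate acquisitions (default 12,
#'   matching the ten-to-fifteen 30-s acquisitions of a measurement).
#' @param seed Optional RNG seed for reproducibility.
#' @param lags Lag grid in seconds (default 140 quasi-log points,
#'   1e-7..0.1 s).
#' @param duration Acquisition duration in seconds (default 30).
#' @return List of `correlation_curve` objects (variance slot zero; use
#'   [average_curves()] to form the weighted average).
#' @export
simulate_fcs_curve <- function(params, noise_level = 0.02, n_replicates = 12,
                               seed = NULL,
                               lags = 10^seq(-7, -1, length.out = 140),
                               duration = 30) {
  stopifnot(inherits(params, "fcs_params"), noise_level >= 0,
            n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  g0 <- fcs_model_g(params, lags)
  sd_lag <- noise_level * (g0 + 1 / sqrt(duration / lags))
  lapply(seq_len(n_replicates), function(i) {
    correlation_curve(lags, g0 + stats::rnorm(length(lags), 0, sd_lag))
  })
}

#' Photon-trace simulation parameters
#'
#' Study-condition defaults emulate the TMR self-quenching measurements: a
#' ~50 nM-scale occupancy (N = 2 molecules in the observation volume), a
#' sub-millisecond diffusion time, microsecond two-state quenching kinetics
#' with equilibrium dark fraction `F = k_to_dark / (k_to_dark + k_to_bright)`
#' and relaxation time `1 / (k_to_dark + k_to_bright)`, and a calibrated
#' observation-volume ratio s = 0.175.
#'
#' @param N Mean occupancy of the observation volume.
#' @param tau_D Diffusion time, seconds.
#' @param s Radial/axial ratio of the observation volume.
#' @param k_to_dark,k_to_bright Telegraph rates, 1/s.
#' @param brightness Detected counts/s per molecule at the PSF center.
#' @param background Background counts/s (summed over both channels).
#' @param duration Trace duration, seconds.
#' @param bin_width Time-bin width, seconds (should be well below the
#'   kinetic relaxation time).
#' @param seed RNG seed.
#' @param box_xy_factor,box_z_factor Periodic-box half-extent in units of
#'   the radial/axial PSF waist (numerical settings; the detection weight at
#'   the default box edge is below 2e-8).
#' @param pos_update_every Advance positions every this many bins with a
#'   rescaled diffusion step (speed knob; kinetics still update every bin).
#' @export
fcs_sim_params <- function(N = 2, tau_D = 4e-4, s = 0.175,
                           k_to_dark = 6e4, k_to_bright = 1.4e5,
                           brightness = 5e5, background = 2e3,
                           duration = 2, bin_width = 5e-7, seed = NULL,
                           box_xy_factor = 10, box_z_factor = 6,
                           pos_update_every = 4) {
  stopifnot(N > 0, tau_D > 0, s > 0, s <= 1, k_to_dark >= 0,
            k_to_bright >= 0, brightness >= 0, background >= 0,
            duration > 0, bin_width > 0)
  k_sum <- k_to_dark + k_to_bright
  if (k_sum > 0) {
    f_dark <- k_to_dark / k_sum
    stopifnot(f_dark < 1)
    if (bin_width > 0.2 / k_sum) {
      warning("bin_width is not small compared with the kinetic relaxation ",
              "time; the correlation at the first lags will be smoothed")
    }
  }
  list(N = N, tau_D = tau_D, s = s, k_to_dark = k_to_dark,
       k_to_bright = k_to_bright, brightness = brightness,
       background = background, duration = duration, bin_width = bin_width,
       seed = seed, box_xy_factor = box_xy_factor,
       box_z_factor = box_z_factor, pos_update_every = pos_update_every)
}

# Geometry shared by the simulator and its closed-form checks. The waist is
# an arbitrary length unit; only ratios of times/volumes matter.
.trace_geometry <- function(p) {
  w_xy <- 0.3
  w_z <- w_xy / p$s
  box_x <- p$box_xy_factor * w_xy
  box_z <- p$box_z_factor * w_z
  v_eff <- pi^1.5 * w_xy^2 * w_z
  v_box <- box_x^2 * box_z
  n_mol <- max(1L, as.integer(round(p$N * v_box / v_eff)))
  d_trans <- w_xy^2 / (4 * p$tau_D)
  list(w_xy = w_xy, w_z = w_z, box_x = box_x, box_z = box_z,
       v_eff = v_eff, v_box = v_box, n_molecules = n_mol,
       step_sd = sqrt(2 * d_trans * p$bin_width))
}

#' Simulate a two-channel photon trace
#'
#' Molecules perform discrete-step Brownian motion in a periodic box; the
#' detection weight is a 3D-Gaussian PSF with axial/radial ratio `s`; each
#' molecule carries a two-state bright/dark telegraph process (exact
#' per-bin propagator); photon counts per bin are Poisson with rate
#' `sum(brightness * PSF * bright_state) + background` and are split
#' binomially (p = 0.5) between the two channels.
#'
#' @param sim_params An [fcs_sim_params()] list.
#' @return List of class `photon_trace`: integer vectors `channel_1`,
#'   `channel_2`, plus `bin_width`, `n_bins`, `params`, `geometry`.
#' @export
simulate_photon_trace <- function(sim_params) {
  p <- sim_params
  if (!is.null(p$seed)) set.seed(p$seed)
  geo <- .trace_geometry(p)
  n_bins <- as.integer(round(p$duration / p$bin_width))
  tr <- .cpp_photon_trace(n_bins, p$bin_width, geo$n_molecules,
                          geo$w_xy, geo$w_z,
                          geo$box_x, geo$box_x, geo$box_z,
                          geo$step_sd, p$k_to_dark, p$k_to_bright,
                          p$brightness, p$background,
                          as.integer(p$pos_update_every))
  structure(list(channel_1 = tr$channel_1, channel_2 = tr$channel_2,
                 bin_width = p$bin_width, n_bins = n_bins,
                 params = p, geometry = geo),
            class = "photon_trace")
}

#' Expected mean count rate of a simulated trace
#'
#' Closed form for the stationary mean rate:
#' `n_molecules * brightness * (1 - F) * <PSF>_box + background`, where
#' `<PSF>_box = (pi/2)^(3/2) w_xy^2 w_z / V_box` is the box-averaged
#' detection weight.
#'
#' @param sim_params An [fcs_sim_params()] list.
#' @return Expected counts/s summed over both channels.
#' @export
expected_count_rate <- function(sim_params) {
  p <- sim_params
  geo <- .trace_geometry(p)
  k_sum <- p$k_to_dark + p$k_to_bright
  f_dark <- if (k_sum > 0) p$k_to_dark / k_sum else 0
  mean_psf <- (pi / 2)^1.5 * geo$w_xy^2 * geo$w_z / geo$v_box
  geo$n_molecules * p$brightness * (1 - f_dark) * mean_psf + p$background
}

#' Multi-tau cross-correlation of two photon channels
#'
#' Computes the normalized cross-correlation
#' `g(tau) = <dI1(t) dI2(t+tau)> / (<I1><I2>)` on a multi-tau lag ladder:
#' `bins_per_level` linear lags at the raw bin width, then factor-2
#' coarsening per level (the standard digital-correlator design). Means are
#' taken symmetrically over the overlap window at each lag.
#'
#' @param trace A `photon_trace`, or `NULL` if channels are given directly.
#' @param channel_1,channel_2 Optional explicit count vectors (equal
#'   length); `bin_width` must then be supplied.
#' @param bin_width Bin width in seconds (taken from `trace` if given).
#' @param n_levels Number of coarsening levels (default 12).
#' @param bins_per_level Linear lags per level (default 16, even).
#' @param correct_finite_box For simulated traces, add the exact
#'   `f_sig^2 / M` finite-box baseline (with `M` the number of simulated
#'   molecules and `f_sig` the molecular fraction of the count rate) to the
#'   normalized correlation. A finite periodic box containing `M` molecules
#'   yields `G = G_ideal - f_sig^2/M`, because the occupancy of the whole
#'   box (unlike an open reservoir) cannot fluctuate; the correction
#'   restores the open-volume curve the analytical model describes.
#'   Ignored when raw channels are supplied. Default `TRUE`.
#' @return A `correlation_curve` (variance zero — average several chunk
#'   correlations with [average_curves()] to estimate it). A trace too
#'   short for the requested ladder yields a truncated ladder with a
#'   warning.
#' @export
multi_tau_correlate <- function(trace = NULL, channel_1 = NULL,
                                channel_2 = NULL, bin_width = NULL,
                                n_levels = 12, bins_per_level = 16,
                                correct_finite_box = TRUE) {
  baseline <- 0
  if (!is.null(trace)) {
    stopifnot(inherits(trace, "photon_trace"))
    channel_1 <- trace$channel_1
    channel_2 <- trace$channel_2
    bin_width <- trace$bin_width
    if (correct_finite_box) {
      rate <- expected_count_rate(trace$params)
      f_sig <- (rate - trace$params$background) / rate
      baseline <- f_sig^2 / trace$geometry$n_molecules
    }
  }
  stopifnot(length(channel_1) == length(channel_2), !is.null(bin_width),
            bins_per_level %% 2 == 0, n_levels >= 1)
  out <- .cpp_multi_tau(as.numeric(channel_1), as.numeric(channel_2),
                        bin_width, as.integer(n_levels),
                        as.integer(bins_per_level))
  if (out$truncated) {
    warning("trace too short for the requested number of levels; ",
            "returning a truncated lag ladder")
  }
  correlation_curve(out$lags, out$g + baseline)
}

#' FRET burst-stream simulation parameters
#'
#' Defaults represent the study conditions of a single-molecule FRET
#' measurement on a double-labeled construct: thousands of events, roughly
#' a hundred detected photons per burst, a donor-only subpopulation, and
#' the instrument corrections beta = 0.6, gamma = 1.2.
#'
#' @param true_eteff True mean transfer efficiency, in \[0, 1).
#' @param n_events Number of burst events (default 3000).
#' @param mean_photons Mean total photons per event (Poisson; default 100).
#' @param donor_only_fraction Fraction of donor-only events (default 0.25).
#' @param background Mean background counts per channel per event.
#' @param beta,gamma Instrument corrections (see [corrections()]).
#' @param seed RNG seed.
#' @export
burst_sim_params <- function(true_eteff, n_events = 3000, mean_photons = 100,
                             donor_only_fraction = 0.25, background = 0.5,
                             beta = 0.6, gamma = 1.2, seed = NULL) {
  stopifnot(true_eteff >= 0, true_eteff < 1, n_events >= 1,
            mean_photons > 0, donor_only_fraction >= 0,
            donor_only_fraction <= 1, background >= 0)
  list(true_eteff = true_eteff, n_events = n_events,
       mean_photons = mean_photons,
       donor_only_fraction = donor_only_fraction, background = background,
       beta = beta, gamma = gamma, seed = seed)
}

#' Simulate a FRET burst stream
#'
#' Per event, total photons are Poisson(`mean_photons`) and the acceptor
#' share is Binomial with success probability `p = f / (1 + f)` where
#' `f = beta + gamma * E / (1 - E)` is the acceptor/donor count ratio that
#' makes the corrected-efficiency estimator recover the true `E` in
#' expectation (gamma detection asymmetry and beta bleed-through are folded
#' in by construction). Donor-only events use `E = 0`. Independent Poisson
#' background counts are added per channel.
#'
#' @param params A [burst_sim_params()] list.
#' @return A [burst_set()] with buffer statistics attached (mean and SD of
#'   the summed background-only signal).
#' @export
simulate_bursts <- function(params) {
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- p$n_events
  donor_only <- stats::runif(n) < p$donor_only_fraction
  e <- ifelse(donor_only, 0, p$true_eteff)
  f <- p$beta + p$gamma * e / (1 - e)
  prob_a <- f / (1 + f)
  total <- stats::rpois(n, p$mean_photons)
  i_a <- stats::rbinom(n, total, prob_a)
  i_d <- total - i_a
  i_a <- i_a + stats::rpois(n, p$background)
  i_d <- i_d + stats::rpois(n, p$background)
  bs <- burst_set(i_d, i_a,
                  buffer_stats = list(mean = 2 * p$background,
                                      sd = sqrt(max(2 * p$background, 1e-12))))
  attr(bs, "sim_params") <- p
  attr(bs, "donor_only") <- donor_only
  bs
}
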