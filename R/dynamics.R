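#' Configuration for intrachain diffusion calculations
#'
#' The intrachain diffusion coefficient follows the
#' Szabo-Schulten-Schulten-type relation `D = 3.545 * Rg^3 / (a * tau_R)`,
#' where `a` is the contact distance at which the TMR dyes quench
#' (default 4 Angstrom, the dye-stacking scale) and `tau_R` the measured
#' end-to-end relaxation time. Both `a` and the prefactor cancel exactly in
#' relative diffusion coefficients, which are normalized to a reference
#' record (default: the LF construct of alpha-synuclein at pH 7.4).
#'
#' @param contact_distance Quenching contact distance `a`, Angstrom (> 0).
#' @param sss_constant Prefactor of the relation (default 3.545).
#' @param reference Named list identifying the normalization record:
#'   `protein`, `construct`, `ph`.
#' @param tau_rec_formula Reconfiguration-time formula; currently
#'   `"msd_over_6d"` (`tau_rec = <r^2> / (6 D)`), pluggable as a function
#'   `f(rms, d_abs)` returning seconds.
#' @param error_mode `"as_printed"` propagates only the Rg^3 error
#'   (`delta_D = (3.545/a) * delta_Rg3 / tau_R` with
#'   `delta_Rg3 = 3 Rg^2 sigma_Rg`); `"quadrature"` additionally folds in
#'   the relative tau_R error in quadrature.
#' @export
dynamics_config <- function(contact_distance = 4, sss_constant = 3.545,
                            reference = list(protein = "alphaS",
                                             construct = "LF", ph = 7.4),
                            tau_rec_formula = "msd_over_6d",
                            error_mode = c("as_printed", "quadrature")) {
  stopifnot(contact_distance > 0, sss_constant > 0)
  error_mode <- match.arg(error_mode)
  list(contact_distance = contact_distance, sss_constant = sss_constant,
       reference = reference, tau_rec_formula = tau_rec_formula,
       error_mode = error_mode)
}

#' Intrachain diffusion coefficient
#'
#' `D = sss_constant * rg^3 / (a * tau_R)`. With `rg` in Angstrom and
#' `tau_R` in seconds the result is in Angstrom^2/s; its absolute value
#' inherits the (uncertain) choices of `R0` and `a` and is only meaningful
#' relative to a reference (see [relative_diffusion()]).
#'
#' @param rg Radius of gyration, Angstrom (> 0).
#' @param tau_r Relaxation time, seconds (> 0).
#' @param config A [dynamics_config()].
#' @export
#' @examples
#' diffusion_coefficient(10, 1e-6) * 1e-6  # Angstrom^2/us
diffusion_coefficient <- function(rg, tau_r, config = dynamics_config()) {
  stopifnot(all(rg > 0), all(tau_r > 0))
  config$sss_constant * rg^3 / (config$contact_distance * tau_r)
}

#' Propagated error of the diffusion coefficient
#'
#' Implements the printed propagation: the error in `Rg^3` is
#' `delta_Rg3 = Rg^3 * 3 * (sigma_Rg / Rg)` and
#' `delta_D = (sss_constant / a) * delta_Rg3 / tau_R`. In `"quadrature"`
#' mode the relative tau_R error is additionally combined in quadrature:
#' `delta_D = D * sqrt((3 sigma_Rg/Rg)^2 + (sigma_tauR/tau_R)^2)`.
#'
#' @param rg,rg_sd Radius of gyration and its SD, Angstrom.
#' @param tau_r,tau_r_sd Relaxation time and its SD, seconds.
#' @param config A [dynamics_config()].
#' @return Error in D, same units as [diffusion_coefficient()].
#' @export
propagate_error <- function(rg, rg_sd, tau_r, tau_r_sd = 0,
                            config = dynamics_config()) {
  stopifnot(all(rg > 0), all(rg_sd >= 0), all(tau_r > 0))
  if (config$error_mode == "quadrature") {
    d <- diffusion_coefficient(rg, tau_r, config)
    d * sqrt((3 * rg_sd / rg)^2 + (tau_r_sd / tau_r)^2)
  } else {
    delta_rg3 <- rg^3 * 3 * (rg_sd / rg)
    (config$sss_constant / config$contact_distance) * delta_rg3 / tau_r
  }
}

#' Reconfiguration time
#'
#' Characteristic time for the segment to diffusively explore its
#' conformational ensemble. Default formula: `tau_rec = <r^2> / (6 D)` with
#' `<r^2>` the mean-square end-to-end distance.
#'
#' @param rms RMS end-to-end distance, Angstrom.
#' @param d_abs Intrachain diffusion coefficient, Angstrom^2/s.
#' @param config A [dynamics_config()]; `tau_rec_formula` may be a function
#'   `f(rms, d_abs)` for alternative definitions.
#' @return Reconfiguration time in seconds.
#' @export
reconfiguration_time <- function(rms, d_abs, config = dynamics_config()) {
  stopifnot(all(rms > 0), all(d_abs > 0))
  f <- config$tau_rec_formula
  if (is.function(f)) return(f(rms, d_abs))
  switch(f,
         msd_over_6d = rms^2 / (6 * d_abs),
         stop("unknown tau_rec_formula: ", f, call. = FALSE))
}

#' Derive relative intrachain diffusion coefficients
#'
#' The full derivation chain: merge a relaxation-time table and a transfer
#' efficiency table on (protein, construct, ph), invert each mean ET_eff to
#' chain dimensions under the Gaussian chain, compute absolute diffusion
#' coefficients, normalize to the reference record, propagate errors, and
#' attach reconfiguration times. By default the raw (linker-uncorrected)
#' RMS feeds D, so relative values are independent of `R0`,
#' `contact_distance` and `sss_constant`; with a linker correction
#' configured the corrected dimensions are used instead.
#'
#' @param tau_table Tibble/data.frame: `protein`, `construct`, `ph`,
#'   `tau_r_us`, `sd_us` (microseconds, as tabulated).
#' @param et_table Tibble/data.frame: `protein`, `construct`, `ph`, `eteff`,
#'   `sd`.
#' @param chain A [gaussian_chain()] model.
#' @param config A [dynamics_config()].
#' @return Tibble with one row per record: chain dimensions, `d_abs`
#'   (Angstrom^2/s), `d_rel`, `delta_d_rel`, `tau_rec_s`, plus the reporting
#'   columns `d_rel_2dp`, `delta_d_rel_2dp`.
#' @export
#' @examples
#' dyn <- derive_dynamics(syn_relaxation_times(), syn_transfer_efficiencies())
#' dyn[dyn$ph == 7.4, c("protein", "construct", "d_rel_2dp")]
derive_dynamics <- function(tau_table, et_table, chain = gaussian_chain(),
                            config = dynamics_config()) {
  validate_table(tau_table, "tau")
  validate_table(et_table, "et")
  merged <- merge(tau_table, et_table, by = c("protein", "construct", "ph"))
  if (nrow(merged) == 0) stop("no overlapping records", call. = FALSE)
  dims <- lapply(seq_len(nrow(merged)), function(i) {
    invert_efficiency(merged$eteff[i], chain, eteff_sd = merged$sd[i])
  })
  use_corrected <- chain$linker_mode != "none"
  merged$rms_raw <- vapply(dims, `[[`, numeric(1), "rms_raw")
  merged$rms <- vapply(dims, `[[`, numeric(1), "rms")
  merged$rg <- if (use_corrected) {
    vapply(dims, `[[`, numeric(1), "rg")
  } else {
    vapply(dims, `[[`, numeric(1), "rg_raw")
  }
  merged$rg_sd <- vapply(dims, `[[`, numeric(1), "rg_sd")
  tau_s <- merged$tau_r_us * 1e-6
  tau_sd_s <- merged$sd_us * 1e-6
  merged$d_abs <- diffusion_coefficient(merged$rg, tau_s, config)
  merged$delta_d <- propagate_error(merged$rg, merged$rg_sd, tau_s, tau_sd_s,
                                    config)
  ref <- config$reference
  is_ref <- merged$protein == ref$protein & merged$construct == ref$construct &
    merged$ph == ref$ph
  if (sum(is_ref) != 1) {
    stop("reference record (", ref$protein, " ", ref$construct, " pH ",
         ref$ph, ") not found exactly once", call. = FALSE)
  }
  d_ref <- merged$d_abs[is_ref]
  merged$d_rel <- merged$d_abs / d_ref
  # reference treated as exact: D_rel(ref) = 1 with zero error
  merged$delta_d_rel <- merged$delta_d / d_ref
  merged$delta_d_rel[is_ref] <- 0
  merged$tau_rec_s <- reconfiguration_time(merged$rms, merged$d_abs, config)
  merged$d_rel_2dp <- round(merged$d_rel, 2)
  merged$delta_d_rel_2dp <- round(merged$delta_d_rel, 2)
  tibble::as_tibble(merged)
}
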