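#' FCS model parameters
#'
#' Parameter set for the autocorrelation model of a fluorescent species
#' diffusing through a 3D-Gaussian observation volume with up to two
#' multiplicative kinetic (self-quenching) relaxation terms:
#' \deqn{G(\tau) = \frac{1}{N}\prod_i\left(1 + A_i e^{-\tau/\tau_{R,i}}\right)
#'   \left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1+\frac{s^2\tau}{\tau_D}\right)^{-1/2}}
#'
#' `A_i` is the amplitude of kinetic term i; the corresponding fraction of
#' molecules in the dark (quenched) state is `F_i = A_i / (1 + A_i)`.
#'
#' @param N Mean occupancy of the observation volume (> 0).
#' @param tau_D Translational diffusion time in seconds (> 0).
#' @param s Radial/axial ratio of the observation volume, in (0, 1].
#' @param kinetic List of kinetic terms, each `c(A = ..., tau_R = ...)`
#'   with `A >= 0` and `tau_R > 0` (seconds); length 0-2.
#' @return Object of class `fcs_params`.
#' @export
#' @examples
#' p <- fcs_params(N = 2, tau_D = 4e-4, s = 0.175,
#'                 kinetic = list(c(A = 0.3, tau_R = 1.2e-6)))
#' fcs_model_g(p, c(1e-7, 1e-5, 1e-3))
fcs_params <- function(N, tau_D, s = 0.175, kinetic = list()) {
  if (!is.numeric(N) || N <= 0) stop("N must be positive", call. = FALSE)
  if (!is.numeric(tau_D) || tau_D <= 0) {
    stop("tau_D must be positive", call. = FALSE)
  }
  if (s <= 0 || s > 1) stop("s must lie in (0, 1]", call. = FALSE)
  if (length(kinetic) > 2) stop("at most two kinetic terms", call. = FALSE)
  for (k in kinetic) {
    if (!all(c("A", "tau_R") %in% names(k))) {
      stop("each kinetic term needs named elements A and tau_R",
           call. = FALSE)
    }
    if (k[["A"]] < 0) stop("kinetic amplitude A must be >= 0", call. = FALSE)
    if (k[["tau_R"]] <= 0) stop("tau_R must be positive", call. = FALSE)
    if (k[["tau_R"]] >= tau_D) {
      warning("tau_R >= tau_D: kinetic and diffusion timescales not separated")
    }
  }
  structure(list(N = N, tau_D = tau_D, s = s, kinetic = kinetic),
            class = "fcs_params")
}

#' Evaluate the FCS autocorrelation model
#'
#' @param params An [fcs_params()] object.
#' @param lag Lag times in seconds (>= 0), vectorized.
#' @return Correlation amplitude G(lag).
#' @export
fcs_model_g <- function(params, lag) {
  stopifnot(inherits(params, "fcs_params"), all(lag >= 0))
  g <- rep(1 / params$N, length(lag))
  for (k in params$kinetic) {
    g <- g * (1 + k[["A"]] * exp(-lag / k[["tau_R"]]))
  }
  x <- lag / params$tau_D
  g / ((1 + x) * sqrt(1 + params$s^2 * x))
}

#' Correlation curve container
#'
#' One (averaged) pseudo-crosscorrelation measurement: lag times, correlation
#' amplitudes, and the per-lag variance across replicate acquisitions.
#'
#' @param lags Lag times in seconds, strictly increasing, > 0.
#' @param g Correlation amplitude at each lag.
#' @param variance Per-lag variance across acquisitions (>= 0); defaults to
#'   zero (unknown).
#' @param n_acquisitions Number of acquisitions averaged.
#' @return Object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, g, variance = rep(0, length(lags)),
                              n_acquisitions = 1L) {
  stopifnot(length(lags) == length(g), length(variance) == length(lags))
  if (any(lags <= 0)) stop("lags must be > 0", call. = FALSE)
  if (any(diff(lags) <= 0)) {
    stop("lags must be strictly increasing", call. = FALSE)
  }
  if (any(variance < 0)) stop("variance must be >= 0", call. = FALSE)
  structure(list(lags = as.numeric(lags), g = as.numeric(g),
                 variance = as.numeric(variance),
                 n_acquisitions = as.integer(n_acquisitions)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags [%.2g..%.2g s], %d acquisition(s)\n",
              length(x$lags), min(x$lags), max(x$lags), x$n_acquisitions))
  invisible(x)
}

#' Average replicate correlation curves
#'
#' Pointwise mean across acquisitions on a shared lag grid; the per-lag
#' sample variance across the replicates becomes the weighting variance for
#' subsequent fitting.
#'
#' @param curves List of `correlation_curve` objects on identical lag grids.
#' @return A single averaged `correlation_curve`.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 2)
  lags <- curves[[1]]$lags
  for (cv in curves) {
    if (length(cv$lags) != length(lags) || any(cv$lags != lags)) {
      stop("curves must share an identical lag grid", call. = FALSE)
    }
  }
  gmat <- vapply(curves, function(cv) cv$g, numeric(length(lags)))
  correlation_curve(lags = lags,
                    g = rowMeans(gmat),
                    variance = apply(gmat, 1, stats::var),
                    n_acquisitions = length(curves))
}

# Weighted residual function shared by fit_fcs_curve and calibrate_s.
# Weights are 1/sd with two stabilizations: the per-lag sample variance
# (noisy at 10-15 acquisitions) is smoothed with a running median across
# neighboring lags, and floored at eps * median(positive variance) so that
# lags with accidentally zero variance cannot dominate. Both operations
# leave uniform variances uniform.
.fcs_weights <- function(curve, eps = 1e-3, smooth_window = 9) {
  v <- curve$variance
  if (all(v == 0)) {
    warning("all variances are zero; using unit weights")
    return(rep(1, length(v)))
  }
  if (smooth_window > 1 && length(v) >= smooth_window) {
    v <- stats::runmed(v, k = smooth_window, endrule = "median")
  }
  floor_v <- eps * stats::median(v[v > 0])
  1 / sqrt(pmax(v, floor_v))
}

.fcs_diagnostics <- function(curve, g_hat, n_par, w) {
  res <- curve$g - g_hat
  ss_res <- sum(res^2)
  ss_tot <- sum((curve$g - mean(curve$g))^2)
  dof <- length(res) - n_par
  list(r_squared = 1 - ss_res / ss_tot,
       reduced_chi_squared = sum((w * res)^2) / dof,
       residuals = res)
}

#' Fit an averaged FCS curve
#'
#' Weighted Levenberg-Marquardt least squares of the diffusion x kinetic
#' model against an averaged curve, with weights `1/variance` (floored; see
#' Details). `s` is held fixed at its calibration value. With
#' `n_kinetic = 0` this is the pure-diffusion fit used for single-labeled
#' control constructs.
#'
#' Fits with `n_kinetic = 2` are additionally restarted from the converged
#' one-component solution (second amplitude seeded near zero) and the lower
#' weighted residual sum is kept, so that the richer model can never fit
#' worse than the nested one.
#'
#' With `fit_offset = TRUE` an additive baseline G_inf is fit alongside the
#' model, the standard remedy for the finite-measurement normalization bias
#' of correlator output (mean-normalized estimates of G sit a small constant
#' below the true curve when the measurement is not much longer than the
#' slowest correlation decay).
#'
#' @param curve A `correlation_curve`.
#' @param n_kinetic Number of kinetic components (0, 1 or 2).
#' @param s_fixed Calibrated observation-volume ratio (see [calibrate_s()]).
#' @param init Optional named list overriding initial guesses
#'   (`N`, `tau_D`, `A`, `tau_R` — for two components give vectors).
#' @param fit_offset Also fit an additive baseline term (default `FALSE`).
#' @param weighting `"variance"` (default) weights residuals by the inverse
#'   per-lag variance, the standard protocol for averaged acquisitions;
#'   `"unit"` uses equal weights. Inverse-variance weights estimated from
#'   the same small replicate set being fit are themselves noisy and
#'   correlate with the residuals, which can bias nonlinear fits; prefer
#'   `"unit"` when only a handful of replicates back the variance estimate
#'   and the noise is far from independent across lags (e.g. correlator
#'   output from few chunks).
#' @return Object of class `fcs_fit`: `params` ([fcs_params()]), `offset`,
#'   `uncertainties`, `r_squared`, `reduced_chi_squared`, `residuals`,
#'   `converged`.
#' @export
fit_fcs_curve <- function(curve, n_kinetic = 1, s_fixed = 0.175, init = NULL,
                          fit_offset = FALSE,
                          weighting = c("variance", "unit")) {
  stopifnot(inherits(curve, "correlation_curve"), n_kinetic %in% 0:2)
  weighting <- match.arg(weighting)
  n_par <- 2 + 2 * n_kinetic + as.integer(fit_offset)
  if (length(curve$lags) <= n_par) {
    stop("curve has too few points for ", n_par, " free parameters",
         call. = FALSE)
  }
  w <- if (weighting == "unit") {
    rep(1, length(curve$lags))
  } else {
    .fcs_weights(curve)
  }
  starts <- .fcs_starts(curve, n_kinetic, init)
  if (fit_offset) starts <- lapply(starts, function(th) c(th, 0))

  run <- function(start) {
    .fcs_lm(curve, w, start, n_kinetic, s_fixed, fit_offset)
  }
  fits <- lapply(starts, run)
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "deviance"))]]
  if (n_kinetic == 2) {
    # restart from the nested one-component optimum
    f1 <- fit_fcs_curve(curve, n_kinetic = 1, s_fixed = s_fixed, init = init,
                        fit_offset = fit_offset, weighting = weighting)
    k1 <- f1$params$kinetic[[1]]
    nested <- c(log(f1$params$N), log(f1$params$tau_D),
                log(max(k1[["A"]], 1e-8)), log(k1[["tau_R"]]),
                log(1e-6), log(k1[["tau_R"]] * 5))
    if (fit_offset) nested <- c(nested, f1$offset)
    fit2 <- run(nested)
    if (fit2$deviance < fit$deviance) fit <- fit2
  }
  fit
}

# Initial guesses: N from 1/G(first lag), tau_D from the half-decay lag,
# tau_R = 1 us, A = 0.3 — plus, because the half-decay heuristic lands
# inside the kinetic decay when the kinetic amplitude is large, a small
# grid of alternative (A, tau_R, tau_D) starts. The fit keeps whichever
# start yields the lowest weighted residual sum.
.fcs_starts <- function(curve, n_kinetic, init) {
  N0 <- if (!is.null(init$N)) init$N else 1 / max(curve$g[1], 1e-12)
  half <- curve$g[1] / 2
  idx <- which(curve$g <= half)[1]
  tauD_half <- if (!is.na(idx)) curve$lags[idx] else max(curve$lags) / 10
  tauD0 <- if (!is.null(init$tau_D)) init$tau_D else tauD_half
  A0 <- rep_len(if (!is.null(init$A)) init$A else 0.3, n_kinetic)
  tauR0 <- rep_len(if (!is.null(init$tau_R)) init$tau_R else
                     1e-6 * seq_len(max(n_kinetic, 1)), n_kinetic)
  pack <- function(tauD, A, tauR) {
    theta <- c(log(N0), log(tauD))
    for (i in seq_len(n_kinetic)) {
      theta <- c(theta, log(max(A[i], 1e-8)), log(tauR[i]))
    }
    theta
  }
  starts <- list(pack(tauD0, A0, tauR0))
  if (is.null(init) && n_kinetic >= 1) {
    tauD_alt <- unique(c(tauD_half, max(curve$lags) / 30,
                         max(curve$lags) / 300))
    for (td in tauD_alt) {
      for (a in c(0.3, 1)) {
        for (tr in c(5e-7, 5e-6)) {
          starts <- c(starts, list(pack(td, rep(a, n_kinetic),
                                        tr * seq_len(n_kinetic))))
        }
      }
    }
  }
  unique(starts)
}

# Parameters are fit on the log scale to enforce positivity; theta is
# clamped so exploratory LM steps cannot overflow/underflow exp().
.fcs_unpack <- function(theta, n_kinetic, s_fixed, fit_offset = FALSE) {
  theta <- pmin(pmax(theta, -60), 60)
  kin <- list()
  for (i in seq_len(n_kinetic)) {
    kin[[i]] <- c(A = exp(theta[2 * i + 1]), tau_R = exp(theta[2 * i + 2]))
  }
  list(params = fcs_params(N = exp(theta[1]), tau_D = exp(theta[2]),
                           s = s_fixed, kinetic = kin),
       offset = if (fit_offset) theta[2 * n_kinetic + 3] else 0)
}

.fcs_lm <- function(curve, w, theta0, n_kinetic, s_fixed,
                    fit_offset = FALSE) {
  resid_fn <- function(theta) {
    u <- suppressWarnings(.fcs_unpack(theta, n_kinetic, s_fixed, fit_offset))
    w * (curve$g - fcs_model_g(u$params, curve$lags) - u$offset)
  }
  out <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  u <- suppressWarnings(.fcs_unpack(out$par, n_kinetic, s_fixed, fit_offset))
  params <- u$params
  g_hat <- fcs_model_g(params, curve$lags) + u$offset
  diag_ <- .fcs_diagnostics(curve, g_hat, length(out$par), w)
  unc <- .fcs_uncertainty(out, params, n_kinetic, fit_offset)
  structure(list(params = params, offset = u$offset, uncertainties = unc,
                 r_squared = diag_$r_squared,
                 reduced_chi_squared = diag_$reduced_chi_squared,
                 residuals = diag_$residuals,
                 converged = out$info %in% 1:4,
                 deviance = out$deviance),
            class = "fcs_fit")
}

.fcs_uncertainty <- function(out, params, n_kinetic, fit_offset = FALSE) {
  # delta method back from the log scale; singular curvature -> NA
  se_log <- tryCatch(sqrt(diag(chol2inv(chol(out$hessian))) * 2 *
                            out$deviance / (length(out$fvec) - length(out$par))),
                     error = function(e) rep(NA_real_, length(out$par)))
  vals <- c(params$N, params$tau_D,
            unlist(lapply(params$kinetic, function(k) c(k[["A"]], k[["tau_R"]]))))
  if (fit_offset) vals <- c(vals, 1)  # offset is fit on the raw scale
  se <- se_log * vals
  nm <- c("N", "tau_D")
  for (i in seq_len(n_kinetic)) nm <- c(nm, paste0(c("A", "tau_R"), i))
  if (fit_offset) nm <- c(nm, "offset")
  stats::setNames(se, nm)
}

#' @export
print.fcs_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<fcs_fit> N = %.4g, tau_D = %.4g s, s = %.3f%s\n", p$N,
              p$tau_D, p$s, if (x$converged) "" else "  [NOT CONVERGED]"))
  for (k in p$kinetic) {
    cat(sprintf("  kinetic: A = %.4g (F = %.3f), tau_R = %.4g s\n",
                k[["A"]], k[["A"]] / (1 + k[["A"]]), k[["tau_R"]]))
  }
  if (!is.null(x$offset) && x$offset != 0) {
    cat(sprintf("  baseline offset = %.3g\n", x$offset))
  }
  cat(sprintf("  R^2 = %.6f, reduced chi^2 = %.4g\n", x$r_squared,
              x$reduced_chi_squared))
  invisible(x)
}

#' Fraction of molecules in the quenched state
#'
#' Converts a kinetic amplitude `A` to the equilibrium dark-state fraction
#' `F = A / (1 + A)` under the two-state quenching model.
#'
#' @param A Kinetic amplitude(s), >= 0.
#' @export
quenched_fraction <- function(A) {
  stopifnot(all(A >= 0))
  A / (1 + A)
}

#' Calibrate the observation-volume ratio from a free-dye curve
#'
#' Fits a pure-diffusion model (no kinetic term) with `s` free to a
#' measurement of a single fast-diffusing dye (e.g. Alexa 594 hydrazide);
#' the returned `s` is then fixed for all sample fits. Curves that a
#' single-species model fits poorly (e.g. mixtures) are flagged.
#'
#' @param curve A `correlation_curve` from a single-species dye measurement.
#' @param chi2_threshold Reduced chi-squared above which the calibration is
#'   flagged as a poor fit.
#' @return List: `s`, `s_se`, `fit` (full diagnostics), `ok`.
#' @export
calibrate_s <- function(curve, chi2_threshold = 10) {
  stopifnot(inherits(curve, "correlation_curve"))
  w <- .fcs_weights(curve)
  half <- curve$g[1] / 2
  idx <- which(curve$g <= half)[1]
  tauD0 <- if (!is.na(idx)) curve$lags[idx] else max(curve$lags) / 10
  theta0 <- c(log(1 / max(curve$g[1], 1e-12)), log(tauD0),
              stats::qlogis(0.2))
  resid_fn <- function(theta) {
    s <- stats::plogis(theta[3])
    p <- fcs_params(N = exp(theta[1]), tau_D = exp(theta[2]), s = s)
    w * (curve$g - fcs_model_g(p, curve$lags))
  }
  out <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  s_hat <- stats::plogis(out$par[3])
  if (s_hat <= 0 || s_hat > 1) stop("calibration failed: s outside (0, 1]")
  params <- fcs_params(N = exp(out$par[1]), tau_D = exp(out$par[2]), s = s_hat)
  g_hat <- fcs_model_g(params, curve$lags)
  diag_ <- .fcs_diagnostics(curve, g_hat, 3, w)
  se_log <- tryCatch(sqrt(diag(chol2inv(chol(out$hessian))) * 2 *
                            out$deviance / (length(out$fvec) - 3)),
                     error = function(e) rep(NA_real_, 3))
  s_se <- se_log[3] * s_hat * (1 - s_hat)  # logistic delta method
  ok <- diag_$reduced_chi_squared <= chi2_threshold && out$info %in% 1:4
  if (!ok) warning("calibration fit is poor (reduced chi^2 = ",
                   signif(diag_$reduced_chi_squared, 3),
                   "); is the sample a single species?")
  list(s = s_hat, s_se = s_se, params = params,
       r_squared = diag_$r_squared,
       reduced_chi_squared = diag_$reduced_chi_squared, ok = ok)
}
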