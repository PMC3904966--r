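#' FRET correction factors
#'
#' Instrument correction factors for corrected transfer efficiencies:
#' `beta` is the donor bleed-through fraction into the acceptor channel and
#' `gamma` corrects for donor/acceptor quantum-yield and detection-efficiency
#' differences. Defaults are the values calibrated for the lab instrument
#' the analysis was designed around (beta = 0.6, gamma = 1.2).
#'
#' @param beta Donor bleed-through fraction (>= 0).
#' @param gamma Quantum-yield/detection factor (> 0).
#' @export
corrections <- function(beta = 0.6, gamma = 1.2) {
  stopifnot(beta >= 0, gamma > 0)
  list(beta = beta, gamma = gamma)
}

#' Burst-selection threshold from buffer statistics
#'
#' Events are accepted when the summed channel signal `I_D + I_A` exceeds
#' `buffer_mean + k * buffer_sd`, separating protein bursts from the
#' buffer-only background.
#'
#' @param buffer_mean,buffer_sd Mean and SD of the summed buffer-only signal.
#' @param k Threshold multiplier (> 0, default 5).
#' @return Threshold in counts.
#' @export
#' @examples
#' select_threshold(2, 1)  # 7
select_threshold <- function(buffer_mean, buffer_sd, k = 5) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  stopifnot(buffer_sd >= 0)
  buffer_mean + k * buffer_sd
}

#' Burst-event container
#'
#' @param i_donor,i_acceptor Per-event donor and acceptor counts (>= 0).
#' @param bin_duration Event bin duration in seconds (metadata).
#' @param buffer_stats Optional list `list(mean = ..., sd = ...)` of the
#'   summed buffer-only signal, used for thresholding.
#' @return A tibble of class `burst_set` with columns `event_id`, `i_donor`,
#'   `i_acceptor`.
#' @export
burst_set <- function(i_donor, i_acceptor, bin_duration = 1e-3,
                      buffer_stats = NULL) {
  stopifnot(length(i_donor) == length(i_acceptor),
            all(i_donor >= 0), all(i_acceptor >= 0))
  out <- tibble::tibble(event_id = seq_along(i_donor),
                        i_donor = as.numeric(i_donor),
                        i_acceptor = as.numeric(i_acceptor))
  attr(out, "bin_duration") <- bin_duration
  attr(out, "buffer_stats") <- buffer_stats
  class(out) <- c("burst_set", class(out))
  out
}

#' Apply a burst threshold
#'
#' Keeps events whose summed signal exceeds the threshold. Set
#' `channel = "per_channel"` to require each channel separately to exceed
#' the threshold instead (the conventional default is the summed channel).
#'
#' @param bursts A [burst_set()].
#' @param threshold Counts threshold (see [select_threshold()]).
#' @param channel `"sum"` (default) or `"per_channel"`.
#' @return Filtered `burst_set`; attribute `n_rejected` records the number
#'   of events removed.
#' @export
apply_threshold <- function(bursts, threshold, channel = c("sum", "per_channel")) {
  channel <- match.arg(channel)
  keep <- if (channel == "sum") {
    bursts$i_donor + bursts$i_acceptor > threshold
  } else {
    bursts$i_donor > threshold & bursts$i_acceptor > threshold
  }
  out <- bursts[keep, ]
  attr(out, "bin_duration") <- attr(bursts, "bin_duration")
  attr(out, "buffer_stats") <- attr(bursts, "buffer_stats")
  attr(out, "n_rejected") <- sum(!keep)
  class(out) <- class(bursts)
  out
}

#' Corrected transfer efficiency per event
#'
#' \deqn{ET_{eff} = \frac{I_A - \beta I_D}{(I_A - \beta I_D) + \gamma I_D}}
#'
#' Values may fall slightly outside \[0, 1\] through shot noise and are
#' retained for histogramming. Events whose corrected denominator is
#' non-positive are returned as `NA` and counted in the `n_excluded`
#' attribute (QC report).
#'
#' @param i_donor,i_acceptor Event counts (vectorized).
#' @param corr A [corrections()] list.
#' @return Numeric vector of efficiencies with attribute `n_excluded`.
#' @export
#' @examples
#' compute_eteff(100, 160)  # 100/220
compute_eteff <- function(i_donor, i_acceptor, corr = corrections()) {
  stopifnot(length(i_donor) == length(i_acceptor),
            all(i_donor >= 0), all(i_acceptor >= 0))
  num <- i_acceptor - corr$beta * i_donor
  den <- num + corr$gamma * i_donor
  bad <- den <= 0
  et <- ifelse(bad, NA_real_, num / den)
  attr(et, "n_excluded") <- sum(bad)
  et
}

#' Bin transfer efficiencies into a histogram
#'
#' @param eteff Per-event efficiencies (`NA`s dropped).
#' @param n_bins Number of bins (default 70).
#' @param range Histogram support (default `c(-0.2, 1.2)`); events outside
#'   are dropped.
#' @return Object of class `eteff_histogram`: `edges`, `mids`, `counts`,
#'   `n_events`.
#' @export
eteff_histogram <- function(eteff, n_bins = 70, range = c(-0.2, 1.2)) {
  eteff <- eteff[!is.na(eteff)]
  eteff <- eteff[eteff >= range[1] & eteff <= range[2]]
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  counts <- graphics::hist(eteff, breaks = edges, plot = FALSE)$counts
  structure(list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_events = length(eteff)),
            class = "eteff_histogram")
}

#' @export
print.eteff_histogram <- function(x, ...) {
  cat(sprintf("<eteff_histogram> %d events in %d bins over [%.2f, %.2f]\n",
              x$n_events, length(x$counts), min(x$edges), max(x$edges)))
  invisible(x)
}

# Area-parameterized Gaussian: A is the area, w the width, xc the center.
.gauss_area <- function(x, A, w, xc) {
  A / (w * sqrt(pi / 2)) * exp(-2 * (x - xc)^2 / w^2)
}

#' Fit a double Gaussian to an efficiency histogram
#'
#' Least-squares fit of the sum of two area-parameterized Gaussians
#' \deqn{y = \sum_{i=1}^{2} \frac{A_i}{w_i\sqrt{\pi/2}}
#'   e^{-2(x - x_{c,i})^2 / w_i^2}}
#' to the binned counts, modeling the donor-only (zero) peak and the FRET
#' (data) peak. The Gaussian with the larger center is deterministically
#' assigned as the data peak; its center is the mean transfer efficiency.
#'
#' @param hist An [eteff_histogram()].
#' @param init Optional named list: `zero_center`, `data_center`, `width`.
#' @return Object of class `double_gaussian_fit`: `peaks` (tibble with
#'   `role`, `area`, `width`, `center`), `mean_et`, `r_squared`,
#'   `converged`, `flagged` (peak collapse / non-convergence).
#' @export
fit_double_gaussian <- function(hist, init = NULL) {
  stopifnot(inherits(hist, "eteff_histogram"))
  x <- hist$mids
  y <- hist$counts
  binw <- diff(hist$edges)[1]
  zc0 <- if (!is.null(init$zero_center)) init$zero_center else 0
  in_data <- x > 0.3
  dc0 <- if (!is.null(init$data_center)) {
    init$data_center
  } else if (any(in_data) && any(y[in_data] > 0)) {
    x[in_data][which.max(y[in_data])]
  } else {
    0.8
  }
  w0 <- if (!is.null(init$width)) init$width else 0.1
  near <- function(c0) sum(y[abs(x - c0) < 2 * w0]) * binw
  theta0 <- c(log(max(near(zc0), binw)), log(w0), zc0,
              log(max(near(dc0), binw)), log(w0), dc0)
  resid_fn <- function(th) {
    y - .gauss_area(x, exp(th[1]), exp(th[2]), th[3]) -
      .gauss_area(x, exp(th[4]), exp(th[5]), th[6])
  }
  out <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  th <- out$par
  converged <- out$info %in% 1:4
  # Degenerate case: an empty zero region leaves nothing for the second
  # Gaussian, which then piles onto the data peak. Detect both centers in
  # the data region and refit a single data Gaussian with an explicitly
  # empty zero peak.
  both_high <- all(th[c(3, 6)] > 0.3)
  if (both_high) {
    single <- function(ths) {
      y - .gauss_area(x, exp(ths[1]), exp(ths[2]), ths[3])
    }
    out1 <- minpack.lm::nls.lm(par = theta0[4:6], fn = single,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-12, ptol = 1e-12))
    th <- c(log(1e-12), log(w0), zc0, out1$par)
    converged <- out1$info %in% 1:4
    resid_fn <- function(ths) single(ths[4:6])
  }
  peaks <- tibble::tibble(area = exp(th[c(1, 4)]), width = exp(th[c(2, 5)]),
                          center = th[c(3, 6)])
  peaks <- peaks[order(peaks$center), ]
  peaks$role <- c("zero", "data")
  collapsed <- !both_high && abs(diff(peaks$center)) < binw
  if (collapsed) warning("peak collapse: centers closer than one bin width")
  y_hat <- resid_fn(th)
  r2 <- 1 - sum(y_hat^2) / sum((y - mean(y))^2)
  structure(list(peaks = peaks[, c("role", "area", "width", "center")],
                 mean_et = peaks$center[peaks$role == "data"],
                 r_squared = r2, converged = converged,
                 flagged = !converged || collapsed),
            class = "double_gaussian_fit")
}

#' @export
print.double_gaussian_fit <- function(x, ...) {
  cat(sprintf("<double_gaussian_fit> mean ET_eff = %.3f (R^2 = %.4f)%s\n",
              x$mean_et, x$r_squared, if (x$flagged) "  [FLAGGED]" else ""))
  print(x$peaks)
  invisible(x)
}

#' Mean transfer efficiency over repeated histograms
#'
#' Arithmetic mean and SD of the data-peak centers across repeated fits
#' (the reporting convention: at least three histograms from at least two
#' sample preparations).
#'
#' @param fits List of `double_gaussian_fit` objects, or a numeric vector of
#'   data-peak centers.
#' @return List: `mean`, `sd`, `n`, plus 2-decimal `mean_2dp`/`sd_2dp`
#'   reporting values.
#' @export
mean_eteff_over_repeats <- function(fits) {
  centers <- if (is.numeric(fits)) {
    fits
  } else {
    vapply(fits, function(f) f$mean_et, numeric(1))
  }
  if (length(centers) < 3) {
    warning("fewer than 3 repeats; mean ET_eff reported anyway")
  }
  m <- mean(centers)
  s <- if (length(centers) > 1) stats::sd(centers) else 0
  list(mean = m, sd = s, n = length(centers),
       mean_2dp = round(m, 2), sd_2dp = round(s, 2))
}
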