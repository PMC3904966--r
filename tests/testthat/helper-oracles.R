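# Independent oracles used across the suite. These are deliberately naive
# (plain loops, explicit enumeration) and share no code with the package
# implementations they check.

# Direct O(N * lags) cross-correlation with the multi-tau estimator's
# definition: symmetric normalization over the overlap window, factor-2
# coarsening between levels.
brute_force_multitau <- function(ch1, ch2, bin_width, n_levels = 12,
                                 bins_per_level = 16) {
  a <- as.numeric(ch1)
  b <- as.numeric(ch2)
  dt <- bin_width
  lags <- numeric(0)
  g <- numeric(0)
  for (level in seq_len(n_levels) - 1) {
    k_lo <- if (level == 0) 1 else bins_per_level / 2 + 1
    if (length(a) <= bins_per_level + 1) break
    for (k in k_lo:bins_per_level) {
      n <- length(a) - k
      sab <- 0; sa <- 0; sb <- 0
      for (t in seq_len(n)) {
        sab <- sab + a[t] * b[t + k]
        sa <- sa + a[t]
        sb <- sb + b[t + k]
      }
      ma <- sa / n; mb <- sb / n
      lags <- c(lags, k * dt)
      g <- c(g, if (ma == 0 || mb == 0) 0 else (sab / n) / (ma * mb) - 1)
    }
    if (level + 1 >= n_levels) break
    half <- length(a) %/% 2
    if (half <= bins_per_level + 1) break
    a2 <- numeric(half); b2 <- numeric(half)
    for (i in seq_len(half)) {
      a2[i] <- a[2 * i - 1] + a[2 * i]
      b2[i] <- b[2 * i - 1] + b[2 * i]
    }
    a <- a2; b <- b2
    dt <- dt * 2
  }
  list(lags = lags, g = g)
}

# Exact two-tailed Mann-Whitney p by explicit enumeration of all group
# labelings; U computed by pair counting (x > y pairs + half ties), not
# rank sums.
oracle_mwu_p <- function(x, y) {
  u_pairs <- function(xs, ys) {
    u <- 0
    for (xi in xs) for (yi in ys) {
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    }
    u
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_pairs(x, y)
  idx_sets <- utils::combn(length(pooled), n1, simplify = FALSE)
  u_all <- vapply(idx_sets, function(ix) {
    u_pairs(pooled[ix], pooled[-ix])
  }, numeric(1))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Plain trapezoid-rule evaluation of the Gaussian-chain mean transfer
# efficiency, independent of stats::integrate.
oracle_mean_efficiency <- function(rms, R0, n = 20000, upper = 10) {
  x <- seq(0, upper, length.out = n)
  fx <- 4 * pi * x^2 * (3 / (2 * pi))^1.5 * exp(-1.5 * x^2) /
    (1 + (x * rms / R0)^6)
  sum((fx[-1] + fx[-n]) / 2) * (x[2] - x[1])
}

# A model curve plus seeded replicates, shared by several fitting tests.
make_noisy_curves <- function(params, seed, n_replicates = 12,
                              noise_level = 0.02) {
  simulate_fcs_curve(params, noise_level = noise_level,
                     n_replicates = n_replicates, seed = seed)
}
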