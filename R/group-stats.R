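#' Exact two-tailed Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic with mid-rank tie handling and a
#' two-tailed p value. For pooled sample sizes `n1 + n2 <= exact_max_n` the
#' null distribution is obtained by exact enumeration of all
#' `choose(n1 + n2, n1)` group labelings of the pooled data (ties handled by
#' mid-ranks inside the enumeration); the two-tailed p is twice the smaller
#' tail probability, capped at 1. Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors of replicate measurements (non-empty).
#' @param alpha Significance level (default 0.05).
#' @param exact_max_n Largest pooled size for exact enumeration (default 16).
#' @return List of class `mwu_result`: `u` (U of the first sample), `p`,
#'   `significant`, `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))$p  # 2/70
mann_whitney_exact <- function(x, y, alpha = 0.05, exact_max_n = 16) {
  stopifnot(length(x) >= 1, length(y) >= 1, is.finite(x), is.finite(y),
            alpha > 0, alpha < 1)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (stats::var(pooled) == 0) {
    warning("all observations tied; p = 1")
    return(structure(list(u = u_obs, p = 1, significant = FALSE,
                          method = "degenerate", n1 = n1, n2 = n2),
                     class = "mwu_result"))
  }
  if (n1 + n2 <= exact_max_n) {
    u_null <- .mwu_null_u(r, n1)
    p_lo <- mean(u_null <= u_obs)
    p_hi <- mean(u_null >= u_obs)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (abs(u_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal"
  }
  structure(list(u = u_obs, p = p, significant = p < alpha, method = method,
                 n1 = n1, n2 = n2),
            class = "mwu_result")
}

# All values of U (for a group of size n1) over every labeling of the pooled
# mid-ranks. combn over indices enumerates the C(n1+n2, n1) labelings.
.mwu_null_u <- function(ranks, n1) {
  idx <- utils::combn(length(ranks), n1)
  colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<mwu_result> U = %.1f (n = %d, %d), p = %.4g [%s]%s\n",
              x$u, x$n1, x$n2, x$p, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Significance-annotated summary table
#'
#' Summarizes replicate measurements per (protein, construct, ph) cell as
#' mean +/- SD and annotates, in the style of the tabulated relaxation-time
#' and efficiency summaries: `*` where a betaS or gammaS cell differs
#' significantly from the alphaS cell of the same construct and pH, and `+`
#' where a cell at pH 3.5 differs from the same protein/construct at pH 7.4
#' (two-tailed exact Mann-Whitney at level `alpha`).
#'
#' @param replicates Long tibble/data.frame: `protein`, `construct`, `ph`,
#'   `value` (one row per replicate measurement).
#' @param alpha Significance level.
#' @param reference_protein Protein against which `*` comparisons run.
#' @return Tibble: `protein`, `construct`, `ph`, `n`, `mean`, `sd`,
#'   `star`, `plus`, `annotation`.
#' @export
significance_table <- function(replicates, alpha = 0.05,
                               reference_protein = "alphaS") {
  req <- c("protein", "construct", "ph", "value")
  if (!all(req %in% names(replicates))) {
    stop("replicates must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cells <- unique(replicates[, c("protein", "construct", "ph")])
  get_vals <- function(p, cst, ph) {
    replicates$value[replicates$protein == p & replicates$construct == cst &
                       replicates$ph == ph]
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$protein[i]; cst <- cells$construct[i]; ph <- cells$ph[i]
    v <- get_vals(p, cst, ph)
    star <- FALSE
    if (p != reference_protein) {
      ref_v <- get_vals(reference_protein, cst, ph)
      if (length(ref_v) > 0) {
        star <- mann_whitney_exact(v, ref_v, alpha)$significant
      }
    }
    plus <- FALSE
    if (ph != 7.4) {
      v74 <- get_vals(p, cst, 7.4)
      if (length(v74) > 0) {
        plus <- mann_whitney_exact(v, v74, alpha)$significant
      }
    }
    data.frame(protein = p, construct = cst, ph = ph, n = length(v),
               mean = mean(v), sd = stats::sd(v), star = star, plus = plus,
               annotation = paste0(if (star) "*" else "",
                                   if (plus) "+" else ""))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
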