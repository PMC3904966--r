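#' Wild-type human synuclein sequences
#'
#' Returns the canonical wild-type sequences of human alpha-, beta- and
#' gamma-synuclein (140, 134 and 127 residues; gamma-synuclein carries
#' valine at position 110) as a named character vector. Sequences are read
#' from the FASTA file bundled with the package.
#'
#' @return Named character vector with elements `alphaS`, `betaS`, `gammaS`.
#' @export
#' @examples
#' nchar(syn_sequences())
syn_sequences <- function() {
  path <- system.file("extdata", "synucleins.fasta", package = "syndyn")
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), " "), `[[`, character(1), 1L)
  seqs
}

#' Labeled-segment construct definitions
#'
#' The thirteen double-labeled constructs: AH (amphipathic-helix region,
#' residues 9-33 in all three proteins), LF (flexible loop, 33-57 in alphaS,
#' 35-59 in betaS/gammaS), NAC (hydrophobic core, 59-83), CT (C-terminal,
#' 92-115 alphaS, 81-105 betaS, 92-117 gammaS) and the proline-rich CT2
#' (102-126, betaS only). Residue numbering is 1-based and ranges are
#' inclusive on both ends; the two boundary residues are the positions
#' mutated to cysteine for dye attachment.
#'
#' @return A tibble with columns `protein_id`, `label`, `start`, `end`.
#' @export
syn_constructs <- function() {
  path <- system.file("extdata", "constructs.csv", package = "syndyn")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seqs <- syn_sequences()
  stopifnot(all(df$protein_id %in% names(seqs)),
            all(df$start >= 1), all(df$start < df$end),
            all(df$end <= nchar(seqs[df$protein_id])))
  tibble::as_tibble(df)
}

#' Extract a wild-type construct segment
#'
#' Returns the wild-type residues spanned by a labeled construct (both
#' endpoint residues included, no cysteine substitutions applied).
#'
#' @param protein_id One of `"alphaS"`, `"betaS"`, `"gammaS"`.
#' @param construct_label One of `"AH"`, `"LF"`, `"NAC"`, `"CT"`, `"CT2"`.
#' @return One-letter amino-acid string of length `end - start + 1`.
#' @export
#' @examples
#' get_segment("alphaS", "NAC")
get_segment <- function(protein_id, construct_label) {
  defs <- syn_constructs()
  row <- defs[defs$protein_id == protein_id & defs$label == construct_label, ]
  if (nrow(row) != 1L) {
    stop("no construct '", construct_label, "' defined for protein '",
         protein_id, "'", call. = FALSE)
  }
  substr(syn_sequences()[[protein_id]], row$start, row$end)
}

#' Ungapped percent identity between two equal-length segments
#'
#' Position-wise comparison of two homologous, equal-length ranges; no
#' alignment is performed. Reported to the nearest integer percent.
#'
#' @param segment_a,segment_b Equal-length amino-acid strings.
#' @return Percent identity in \[0, 100\].
#' @export
#' @examples
#' percent_identity(get_segment("alphaS", "AH"), get_segment("betaS", "AH"))
percent_identity <- function(segment_a, segment_b) {
  a <- .split_residues(segment_a)
  b <- .split_residues(segment_b)
  if (length(a) != length(b)) {
    stop("segments have different lengths (", length(a), " vs ", length(b),
         "); compare equal-length homologous ranges", call. = FALSE)
  }
  round(100 * sum(a == b) / length(a))
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.split_residues <- function(segment) {
  stopifnot(is.character(segment), length(segment) == 1L, nzchar(segment))
  res <- strsplit(toupper(segment), "")[[1]]
  bad <- setdiff(unique(res), .AA20)
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res
}

# Zimmerman bulkiness (side-chain steric scale) and Kyte-Doolittle
# hydropathy, per residue.
.ZIMMERMAN <- c(A = 11.50, R = 14.28, N = 12.82, D = 11.68, C = 13.46,
                Q = 14.45, E = 13.57, G = 3.40,  H = 13.69, I = 21.40,
                L = 21.40, K = 15.71, M = 16.25, F = 19.80, P = 17.43,
                S = 9.47,  T = 15.77, W = 21.67, Y = 18.03, V = 21.57)

.KYTE_DOOLITTLE <- c(A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Per-residue physico-chemical scales
#'
#' Returns a residue scale as a list with elements `name`, `values` (named
#' numeric, all 20 canonical residues) and `normalizer` (scalar divisor
#' applied to the per-residue mean). Bulkiness uses the Zimmerman scale
#' normalized to the glycine value 3.40, so poly-glycine scores exactly 1;
#' hydrophobicity uses the Kyte-Doolittle scale unnormalized.
#'
#' @param name `"bulkiness"` or `"hydrophobicity"`.
#' @export
#' @examples
#' mean_scale(get_segment("betaS", "NAC"), residue_scale("bulkiness"))
residue_scale <- function(name = c("bulkiness", "hydrophobicity")) {
  name <- match.arg(name)
  if (name == "bulkiness") {
    list(name = name, values = .ZIMMERMAN, normalizer = .ZIMMERMAN[["G"]])
  } else {
    list(name = name, values = .KYTE_DOOLITTLE, normalizer = 1.0)
  }
}

#' Mean scale score per residue of a segment
#'
#' @param segment Amino-acid string.
#' @param scale A scale from [residue_scale()].
#' @return `(mean of per-residue scores) / normalizer`.
#' @export
mean_scale <- function(segment, scale) {
  res <- .split_residues(segment)
  mean(scale$values[res]) / scale$normalizer
}

#' Side-chain ionization model
#'
#' Henderson-Hasselbalch charge model over the titratable side chains.
#' Default pKa set: D 3.65, E 4.25, H 6.00, C 8.30, Y 10.07, K 10.53,
#' R 12.48; chain termini are excluded by default (the labeled segments sit
#' inside the full-length protein, so the segment has no free termini).
#'
#' @param pka Named numeric vector of side-chain pKa values.
#' @param include_termini Include free alpha-amino/alpha-carboxyl groups
#'   (pKa 9.0 and 2.0). Default `FALSE`.
#' @export
charge_model <- function(pka = c(D = 3.65, E = 4.25, H = 6.00, C = 8.30,
                                 Y = 10.07, K = 10.53, R = 12.48),
                         include_termini = FALSE) {
  stopifnot(all(pka > 0))
  list(pka = pka, include_termini = include_termini)
}

#' Net charge per residue of a segment
#'
#' Sums fractional Henderson-Hasselbalch side-chain charges at the given pH
#' (acidic residues D, E, C, Y contribute `-1/(1 + 10^(pKa - pH))`; basic
#' residues H, K, R contribute `+1/(1 + 10^(pH - pKa))`) and divides by the
#' segment length.
#'
#' @param segment Amino-acid string.
#' @param ph Solution pH, in (0, 14).
#' @param model A [charge_model()].
#' @return List with `net` (signed charge per residue) and `abs` (its
#'   absolute value).
#' @export
#' @examples
#' charge_per_residue(get_segment("betaS", "CT"), 7.4)
charge_per_residue <- function(segment, ph, model = charge_model()) {
  stopifnot(ph > 0, ph < 14)
  res <- .split_residues(segment)
  acidic <- c("D", "E", "C", "Y")
  basic <- c("H", "K", "R")
  q <- 0
  for (r in res) {
    if (r %in% names(model$pka)) {
      if (r %in% acidic) {
        q <- q - 1 / (1 + 10^(model$pka[[r]] - ph))
      } else if (r %in% basic) {
        q <- q + 1 / (1 + 10^(ph - model$pka[[r]]))
      }
    }
  }
  if (model$include_termini) {
    q <- q + 1 / (1 + 10^(ph - 9.0)) - 1 / (1 + 10^(2.0 - ph))
  }
  net <- q / length(res)
  list(net = net, abs = abs(net))
}

#' Physico-chemical property table for all constructs
#'
#' Net charge per residue (signed and absolute, at each requested pH),
#' glycine-normalized Zimmerman bulkiness and Kyte-Doolittle hydrophobicity
#' per residue, for every construct definition.
#'
#' @param ph Numeric vector of pH values (default the two study conditions,
#'   7.4 and 3.5).
#' @param model A [charge_model()].
#' @return Long tibble: `protein`, `construct`, `ph`, `charge_per_residue`,
#'   `abs_charge_per_residue`, `bulkiness_per_residue`,
#'   `hydrophobicity_per_residue` (bulkiness and hydrophobicity are pH
#'   independent and repeated per pH row).
#' @export
construct_properties <- function(ph = c(7.4, 3.5), model = charge_model()) {
  defs <- syn_constructs()
  bulk <- residue_scale("bulkiness")
  hyd <- residue_scale("hydrophobicity")
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    seg <- get_segment(defs$protein_id[i], defs$label[i])
    b <- mean_scale(seg, bulk)
    h <- mean_scale(seg, hyd)
    do.call(rbind, lapply(ph, function(p) {
      ch <- charge_per_residue(seg, p, model)
      data.frame(protein = defs$protein_id[i], construct = defs$label[i],
                 ph = p, charge_per_residue = ch$net,
                 abs_charge_per_residue = ch$abs,
                 bulkiness_per_residue = b, hydrophobicity_per_residue = h)
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
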