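#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed order used throughout the
#' package for every per-residue vector and every profile column:
#' A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V.
#'
#' @return Character vector of length 20 (one-letter codes).
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ORDER

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

#' Taylor overlapping amino-acid property classes
#'
#' The ten overlapping stereo-chemical classes of Taylor's Venn diagram, in
#' the fixed order used for the 10-bit overlapping-property (OP) encoding
#' and for the Venn-diagram relative-entropy (RVD) conservation score:
#' Polar, Positive, Negative, Charged, Hydrophobic, Aliphatic, Aromatic,
#' Small, Tiny, Proline.  Classes overlap: a residue may belong to several.
#'
#' @return Named list of ten character vectors of one-letter residue codes.
#' @export
#' @examples
#' aa_classes()$Charged
aa_classes <- function() AA_CLASSES

AA_CLASSES <- list(
  Polar       = c("N", "Q", "S", "D", "E", "C", "T", "K", "R", "H", "Y", "W"),
  Positive    = c("K", "H", "R"),
  Negative    = c("D", "E"),
  Charged     = c("K", "H", "R", "D", "E"),
  Hydrophobic = c("A", "G", "C", "T", "I", "V", "L", "K", "H", "F", "Y", "W", "M"),
  Aliphatic   = c("I", "V", "L"),
  Aromatic    = c("F", "Y", "W", "H"),
  Small       = c("P", "N", "D", "T", "C", "A", "G", "S", "V"),
  Tiny        = c("A", "S", "G", "C"),
  Proline     = "P"
)

# 10 x 20 logical membership matrix, classes in rows, canonical columns
AA_CLASS_MATRIX <- local({
  m <- vapply(AA_CLASSES, function(cls) AA_ORDER %in% cls, logical(20L))
  t(m) * 1L
})

#' BLOSUM62 amino-acid background distribution
#'
#' The Robinson-Robinson background frequencies distributed with the
#' BLOSUM62 substitution data, renormalised to sum to exactly 1, in the
#' canonical alphabet order.  Used as the background q of the
#' Jensen-Shannon divergence conservation score and, summed over the
#' Taylor classes, as the class background of the RVD score.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' sum(aa_background())
aa_background <- function() AA_BACKGROUND

# Robinson & Robinson frequencies as shipped with BLOSUM62
AA_BACKGROUND <- local({
  q <- c(A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640,
         C = 0.019246, Q = 0.042644, E = 0.062949, G = 0.073832,
         H = 0.021992, I = 0.051420, L = 0.090191, K = 0.057438,
         M = 0.022425, F = 0.038556, P = 0.052028, S = 0.071198,
         T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
  q <- q[AA_ORDER]
  q / sum(q)
})

# Per-class background mass Q_c = sum over class members of q_a
AA_CLASS_BACKGROUND <- drop(AA_CLASS_MATRIX %*% AA_BACKGROUND)

#' Sweet-Eisenberg hydrophobicity scale
#'
#' The optimal matching hydrophobicity (OMH) index of Sweet & Eisenberg
#' (1983), used by the averaged cumulative hydrophobicity (ACH) channel.
#' Non-canonical letters score 0.
#'
#' @return Named numeric vector of length 20 in canonical alphabet order.
#' @export
#' @examples
#' aa_hydrophobicity()[["F"]]
aa_hydrophobicity <- function() AA_HYDROPHOBICITY

AA_HYDROPHOBICITY <- c(
  A = -0.40, R = -0.59, N = -0.92, D = -1.31, C =  0.17,
  Q = -0.91, E = -1.22, G = -0.67, H = -0.64, I =  1.25,
  L =  1.22, K = -0.67, M =  1.02, F =  1.92, P = -0.49,
  S = -0.55, T = -0.28, W =  0.50, Y =  0.23, V =  0.91
)

# residue letter -> canonical index (NA for non-canonical); fast lookup
aa_index <- function(letters) match(letters, AA_ORDER)

split_residues <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
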