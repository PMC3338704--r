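# x * log2(x / y) with the 0 * log 0 = 0 convention
xlogx_ratio <- function(x, y) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log2(x[nz] / y[nz])
  out
}

#' Normalise a profile column to a residue distribution
#'
#' Converts one row of a weighted-observed-percentage matrix into a
#' probability vector over the 20 residues.  All-zero rows carry no
#' conservation evidence and fall back to the background distribution
#' (which scores 0 under both JSD and RVD).
#'
#' @param wop_row Numeric vector of 20 non-negative percentages.
#' @param background Length-20 background distribution; default
#'   [aa_background()].
#' @return Length-20 probability vector summing to 1.
#' @export
column_distribution <- function(wop_row, background = aa_background()) {
  if (length(wop_row) != 20L) stop_validation("wop_row must have 20 entries")
  if (any(wop_row < 0)) stop_validation("negative weighted observed percentage")
  s <- sum(wop_row)
  if (s <= 0) return(background)
  unname(wop_row) / s
}

check_distribution <- function(p, name) {
  if (length(p) != 20L || any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop_validation(sprintf("%s is not a valid distribution over 20 residues", name))
  }
}

#' Jensen-Shannon divergence conservation score
#'
#' The Capra-Singh Jensen-Shannon divergence between a profile column
#' distribution `p` and a background `q`:
#' `lambda_mix * KL(p || r) + (1 - lambda_mix) * KL(q || r)` with
#' `r = lambda_mix * p + (1 - lambda_mix) * q`, logarithms base 2, so the
#' score lies in \[0, 1\] and is 0 exactly when `p = q`.
#'
#' @param p,q Length-20 probability vectors.
#' @param lambda_mix Mixture weight in (0, 1); default 0.5 (the symmetric
#'   divergence).
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' jsd_score(aa_background(), aa_background())
jsd_score <- function(p, q, lambda_mix = 0.5) {
  check_distribution(p, "p")
  check_distribution(q, "q")
  stopifnot(lambda_mix > 0, lambda_mix < 1)
  r <- lambda_mix * p + (1 - lambda_mix) * q
  val <- lambda_mix * sum(xlogx_ratio(p, r)) +
    (1 - lambda_mix) * sum(xlogx_ratio(q, r))
  min(max(val, 0), 1)
}

#' Venn-diagram relative-entropy conservation score (RVD)
#'
#' Sums, over the ten overlapping Taylor property classes, the
#' relative-entropy terms `P_c * log2(P_c / Q_c)` where `P_c` is the
#' profile-column mass of class `c` and `Q_c` the background mass.
#' Because the classes overlap this is a sum of per-class terms, not a KL
#' divergence over a partition; it is 0 at the background, unbounded above,
#' and can dip slightly below 0 for columns flatter than the background
#' (the per-chain min-max normalisation downstream absorbs this).
#'
#' @param p Length-20 probability vector (a profile column distribution).
#' @param background Length-20 background distribution.
#' @return A single number.
#' @export
rvd_score <- function(p, background = aa_background()) {
  check_distribution(p, "p")
  P_c <- drop(AA_CLASS_MATRIX %*% p)
  Q_c <- if (identical(background, AA_BACKGROUND)) AA_CLASS_BACKGROUND
         else drop(AA_CLASS_MATRIX %*% background)
  sum(xlogx_ratio(P_c, Q_c))
}

#' Min-max normalise a per-residue track
#'
#' @param values Finite numeric vector (one value per residue of a chain).
#' @return `(values - min) / (max - min)`, or all zeros when the track is
#'   constant.
#' @export
normalize_track <- function(values) {
  if (length(values) == 0L) return(numeric())
  if (any(!is.finite(values))) stop_validation("non-finite value in track")
  rng <- range(values)
  if (rng[2] == rng[1]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Combined conservation score (VJSD)
#'
#' Arithmetic mean of the per-chain min-max-normalised RVD and JSD scores
#' of a site.
#'
#' @param rvd_norm,jsd_norm Normalised scores in \[0, 1\].
#' @return `(rvd_norm + jsd_norm) / 2`.
#' @export
vjsd_score <- function(rvd_norm, jsd_norm) {
  if (any(rvd_norm < -1e-9 | rvd_norm > 1 + 1e-9) ||
      any(jsd_norm < -1e-9 | jsd_norm > 1 + 1e-9)) {
    stop_validation("vjsd_score inputs must lie in [0, 1]")
  }
  (rvd_norm + jsd_norm) / 2
}

#' Per-residue conservation scores for one chain
#'
#' Computes the JSD and RVD conservation scores of every profile column,
#' their per-chain min-max normalisations, and the combined VJSD score.
#'
#' @param wop L x 20 weighted-observed-percentage matrix (canonical column
#'   order), e.g. from [read_wop_pssm()].
#' @param background Length-20 background distribution.
#' @param lambda_mix Mixture weight of the Jensen-Shannon divergence.
#' @return A tibble with columns `position`, `jsd`, `rvd`, `jsd_norm`,
#'   `rvd_norm`, `vjsd`.
#' @export
conservation_scores <- function(wop, background = aa_background(),
                                lambda_mix = 0.5) {
  if (ncol(wop) != 20L) stop_validation("wop must have 20 columns")
  L <- nrow(wop)
  jsd <- numeric(L)
  rvd <- numeric(L)
  for (i in seq_len(L)) {
    p <- column_distribution(wop[i, ], background)
    jsd[i] <- jsd_score(p, background, lambda_mix)
    rvd[i] <- rvd_score(p, background)
  }
  jsd_norm <- normalize_track(jsd)
  rvd_norm <- normalize_track(rvd)
  tibble::tibble(position = seq_len(L), jsd = jsd, rvd = rvd,
                 jsd_norm = jsd_norm, rvd_norm = rvd_norm,
                 vjsd = vjsd_score(rvd_norm, jsd_norm))
}
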