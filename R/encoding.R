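#' Residue-type one-hot encoding (RT)
#'
#' Encodes residues as 20-bit indicator vectors in the canonical alphabet
#' order, e.g. A -> 1 followed by nineteen 0s and V -> nineteen 0s followed
#' by 1.  Non-canonical letters (B, Z, X, U, O, ...) encode as all zeros.
#'
#' @param residues Character vector of one-letter residue codes.
#' @return A `length(residues)` x 20 binary matrix with columns named by
#'   three-letter residue codes (`RT-Ala`, ..., `RT-Val`).
#' @export
#' @examples
#' encode_rt("A")
encode_rt <- function(residues) {
  idx <- aa_index(residues)
  m <- matrix(0L, nrow = length(residues), ncol = 20L,
              dimnames = list(NULL, paste0("RT-", AA_THREE)))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1L
  m
}

#' Overlapping-property encoding (OP)
#'
#' Encodes residues as 10-bit indicators over the Taylor property classes
#' in the order Polar, Positive, Negative, Charged, Hydrophobic,
#' Aliphatic, Aromatic, Small, Tiny, Proline.  Classes overlap, so several
#' bits may be set.  Non-canonical letters encode as all zeros.
#'
#' @param residues Character vector of one-letter residue codes.
#' @return A `length(residues)` x 10 binary matrix with columns `OP-Polar`,
#'   ..., `OP-Proline`.
#' @export
#' @examples
#' encode_op("V")
encode_op <- function(residues) {
  idx <- aa_index(residues)
  m <- matrix(0L, nrow = length(residues), ncol = 10L,
              dimnames = list(NULL, paste0("OP-", names(AA_CLASSES))))
  ok <- !is.na(idx)
  if (any(ok)) m[ok, ] <- t(AA_CLASS_MATRIX)[idx[ok], , drop = FALSE]
  m
}

ACH_WINDOWS <- seq(3L, 21L, by = 2L)

#' Averaged cumulative hydrophobicity profile (ACH)
#'
#' For every residue, the mean Sweet-Eisenberg hydrophobicity index over
#' centred windows of sizes 3, 5, ..., 21.  Window positions falling
#' outside the sequence contribute 0 to the sum while the divisor stays the
#' full window size; non-canonical letters also contribute 0.
#'
#' @param sequence Amino-acid sequence string.
#' @return An L x 10 numeric matrix with columns `ACH-Win3`, ...,
#'   `ACH-Win21`.
#' @export
ach_profile <- function(sequence) {
  res <- split_residues(sequence)
  L <- length(res)
  if (L == 0L) stop_validation("empty sequence")
  h <- AA_HYDROPHOBICITY[res]
  h[is.na(h)] <- 0
  # prefix sums with zero padding outside the chain
  cs <- c(0, cumsum(h))
  out <- matrix(0, nrow = L, ncol = length(ACH_WINDOWS),
                dimnames = list(NULL, paste0("ACH-Win", ACH_WINDOWS)))
  pos <- seq_len(L)
  for (k in seq_along(ACH_WINDOWS)) {
    half <- (ACH_WINDOWS[k] - 1L) %/% 2L
    lo <- pmax(pos - half, 1L)
    hi <- pmin(pos + half, L)
    out[, k] <- (cs[hi + 1L] - cs[lo]) / ACH_WINDOWS[k]
  }
  out
}

CHANNELS <- c("RT", "OP", "ACH", "SS", "ASA", "JSD", "VJSD", "Consurf")
CENTRAL_CHANNELS <- c("RT", "OP", "ACH")
WINDOWED_CHANNELS <- c("SS", "ASA", "JSD", "VJSD", "Consurf")

channel_slot_names <- function(channel, offset = NULL) {
  switch(channel,
         RT = paste0("RT-", AA_THREE),
         OP = paste0("OP-", names(AA_CLASSES)),
         ACH = paste0("ACH-Win", ACH_WINDOWS),
         SS = sprintf("SS%+d-%s", offset, c("H", "E", "C")),
         ASA = sprintf("ASA%+d", offset),
         JSD = sprintf("JSD%+d", offset),
         VJSD = sprintf("VJSD%+d", offset),
         Consurf = sprintf("Consurf%+d", offset))
}

#' Sliding-window feature layout
#'
#' Defines the column layout of a classifier feature vector: the central
#' residue's RT (20 bits), OP (10 bits) and ACH (10 values), then for each
#' window offset -w, ..., +w the windowed channels SS (3), ASA (1),
#' JSD (1), VJSD (1) and Consurf (1).  With all eight channels the
#' dimension is `40 + 7 * (2w + 1)`.
#'
#' @param window Non-negative integer window half-width w.
#' @param channels Channels to include (default all eight); dropping a
#'   channel removes its slots, as in the leave-one-attribute-out
#'   experiments.
#' @return A `catsite_layout` with fields `window`, `channels`, `slots`
#'   (column names in order) and `dim`.
#' @export
#' @examples
#' window_layout(6)$dim
window_layout <- function(window, channels = CHANNELS) {
  window <- as.integer(window)
  if (is.na(window) || window < 0L) stop_validation("window must be a non-negative integer")
  bad <- setdiff(channels, CHANNELS)
  if (length(bad) > 0L) {
    stop_validation(sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")))
  }
  channels <- CHANNELS[CHANNELS %in% channels]
  slots <- character()
  for (ch in intersect(CENTRAL_CHANNELS, channels)) {
    slots <- c(slots, channel_slot_names(ch))
  }
  for (offset in seq(-window, window)) {
    for (ch in intersect(WINDOWED_CHANNELS, channels)) {
      slots <- c(slots, channel_slot_names(ch, offset))
    }
  }
  structure(list(window = window, channels = channels, slots = slots,
                 dim = length(slots)),
            class = "catsite_layout")
}

#' @export
print.catsite_layout <- function(x, ...) {
  cat(sprintf("<catsite_layout> window %d, %d channels (%s), dimension %d\n",
              x$window, length(x$channels), paste(x$channels, collapse = ", "),
              x$dim))
  invisible(x)
}

#' Per-residue feature table for one chain
#'
#' Populates all eight per-residue channels for a chain: the RT/OP one-hot
#' encodings, the ACH hydrophobicity profile, the (H, E, C)
#' secondary-structure probabilities, the binary solvent accessibility,
#' the JSD conservation score, the combined VJSD score, and the (by
#' default per-chain min-max-normalised) Consurf score.
#'
#' @param chain_id Chain identifier.
#' @param sequence Amino-acid sequence string of length L.
#' @param wop L x 20 weighted-observed-percentage matrix.
#' @param ss L x 3 secondary-structure matrix in (H, E, C) order.
#' @param asa Length-L 0/1 accessibility vector.
#' @param consurf Length-L conservation scores.
#' @param background Background residue distribution.
#' @param normalize_consurf Min-max normalise the Consurf channel per
#'   chain (default TRUE; raw scores from different sources are not on a
#'   common scale).
#' @return A `catsite_features` object holding the channel matrices.
#' @export
build_feature_table <- function(chain_id, sequence, wop, ss, asa, consurf,
                                background = aa_background(),
                                normalize_consurf = TRUE) {
  L <- nchar(sequence)
  check_len <- function(n, what) {
    if (n != L) {
      stop_validation(sprintf(
        "chain %s: %s has length %d but sequence has length %d",
        chain_id, what, n, L))
    }
  }
  check_len(nrow(wop), "WOP profile")
  check_len(nrow(ss), "secondary-structure track")
  check_len(length(asa), "accessibility track")
  check_len(length(consurf), "Consurf track")
  if (!all(asa %in% c(0L, 1L))) {
    stop_validation(sprintf("chain %s: accessibility track is not binary", chain_id))
  }
  res <- split_residues(sequence)
  cons <- conservation_scores(wop, background)
  structure(list(
    chain_id = chain_id,
    residues = res,
    length = L,
    rt = encode_rt(res),
    op = encode_op(res),
    ach = ach_profile(sequence),
    ss = unclass(ss)[, c("H", "E", "C"), drop = FALSE],
    asa = as.numeric(asa),
    jsd = cons$jsd,
    vjsd = cons$vjsd,
    consurf = if (normalize_consurf) normalize_track(consurf) else as.numeric(consurf)
  ), class = "catsite_features")
}

#' @export
print.catsite_features <- function(x, ...) {
  cat(sprintf("<catsite_features> chain %s, %d residues, 8 channels\n",
              x$chain_id, x$length))
  invisible(x)
}

# L x 7 matrix of the windowed channel values, columns SS-H, SS-E, SS-C,
# ASA, JSD, VJSD, Consurf; rows outside [1, L] are handled by the caller.
windowed_matrix <- function(features) {
  cbind(features$ss, features$asa, features$jsd, features$vjsd,
        features$consurf)
}

WINDOWED_COL_INDEX <- list(SS = 1:3, ASA = 4L, JSD = 5L, VJSD = 6L, Consurf = 7L)

#' Assemble the classifier vector for one residue
#'
#' Fills the central RT/OP/ACH slots from the residue itself and the
#' windowed slots from offsets -w, ..., +w, with all-zero blocks for
#' offsets falling outside the chain (the terminus zero-fill rule).
#'
#' @param features A `catsite_features` object.
#' @param position 1-based residue position.
#' @param layout A `catsite_layout`.
#' @return Named numeric vector of length `layout$dim`.
#' @export
assemble_window <- function(features, position, layout) {
  if (position < 1L || position > features$length) {
    stop_validation(sprintf("position %d out of range for chain %s (length %d)",
                            position, features$chain_id, features$length))
  }
  wm <- windowed_matrix(features)
  wcols <- unlist(WINDOWED_COL_INDEX[intersect(WINDOWED_CHANNELS, layout$channels)],
                  use.names = FALSE)
  out <- numeric(0)
  if ("RT" %in% layout$channels) out <- c(out, features$rt[position, ])
  if ("OP" %in% layout$channels) out <- c(out, features$op[position, ])
  if ("ACH" %in% layout$channels) out <- c(out, features$ach[position, ])
  w <- layout$window
  if (length(wcols) > 0L) {
    for (offset in seq(-w, w)) {
      p <- position + offset
      vals <- if (p >= 1L && p <= features$length) wm[p, wcols] else numeric(length(wcols))
      out <- c(out, vals)
    }
  }
  stats::setNames(out, layout$slots)
}

#' Assemble a windowed training/prediction dataset
#'
#' Builds the feature matrix for a selection of (chain, position) pairs,
#' keeping the chain of every row for group-aware cross-validation.
#'
#' @param features_list Named list of `catsite_features`, one per chain.
#' @param selected A data frame with columns `chain_id`, `position` and
#'   optionally `label` (+1 catalytic / -1 non-catalytic).
#' @param layout A `catsite_layout`.
#' @return A `catsite_dataset` with fields `X` (N x d matrix), `y`
#'   (+1/-1 or NA), `groups` (chain ids), `positions` and `layout`.
#' @export
build_dataset <- function(features_list, selected, layout) {
  if (is.null(names(features_list))) {
    names(features_list) <- vapply(features_list, `[[`, character(1L), "chain_id")
  }
  unknown <- setdiff(unique(selected$chain_id), names(features_list))
  if (length(unknown) > 0L) {
    stop_validation(sprintf("selection references unknown chain(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  dup <- duplicated(selected[c("chain_id", "position")])
  if (any(dup)) stop_validation("duplicated (chain, position) in selection")
  n <- nrow(selected)
  X <- matrix(0, nrow = n, ncol = layout$dim,
              dimnames = list(NULL, layout$slots))
  for (i in seq_len(n)) {
    X[i, ] <- assemble_window(features_list[[selected$chain_id[i]]],
                              selected$position[i], layout)
  }
  y <- if ("label" %in% names(selected)) as.numeric(selected$label) else rep(NA_real_, n)
  if (!all(is.na(y)) && !all(y %in% c(-1, 1))) {
    stop_validation("labels must be +1 or -1")
  }
  structure(list(X = X, y = y, groups = selected$chain_id,
                 positions = selected$position, layout = layout),
            class = "catsite_dataset")
}

#' @export
print.catsite_dataset <- function(x, ...) {
  cat(sprintf("<catsite_dataset> %d rows x %d features (window %d), %d chains, %d positive\n",
              nrow(x$X), ncol(x$X), x$layout$window,
              length(unique(x$groups)), sum(x$y == 1, na.rm = TRUE)))
  invisible(x)
}
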