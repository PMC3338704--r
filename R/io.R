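#' Read protein chains from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with one row per entry and columns `chain_id` (the first
#'   whitespace-delimited token of the header) and `sequence` (uppercased).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">X demo", "ACDE"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  check_file_exists(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(chain_id = character(), sequence = character()))
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop_format(sprintf("FASTA entry with empty sequence: '%s'",
                        headers[which(empty)[1L]]))
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  tibble::tibble(chain_id = ids, sequence = unname(seqs))
}

#' Write protein chains to a FASTA file
#'
#' @param chains A data frame with columns `chain_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  set <- Biostrings::BStringSet(chains$sequence)
  names(set) <- chains$chain_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read catalytic-site annotations
#'
#' Reads a tab-separated annotation table with a header line and columns
#' `chain_id`, `position` (1-based) and `residue` (the expected one-letter
#' code at that position).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chain_id`, `position`, `residue`.
#' @export
read_annotations <- function(path) {
  check_file_exists(path)
  df <- utils::read.delim(path, colClasses = c("character", "integer", "character"))
  if (!identical(names(df), c("chain_id", "position", "residue"))) {
    stop_format(sprintf(
      "annotation file must have columns chain_id, position, residue; found: %s",
      paste(names(df), collapse = ", ")))
  }
  dup <- duplicated(df[c("chain_id", "position")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop_validation(sprintf("duplicate annotation for chain %s position %d",
                            df$chain_id[i], df$position[i]))
  }
  tibble::as_tibble(df)
}

#' @rdname read_annotations
#' @param annotations A data frame with columns `chain_id`, `position`,
#'   `residue`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[c("chain_id", "position", "residue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach catalytic-site labels to chains
#'
#' Joins an annotation table onto a chain table, validating that every
#' annotated position lies inside its chain and warning when the annotated
#' residue letter disagrees with the sequence.
#'
#' @param chains A tibble from [read_fasta()].
#' @param annotations A tibble from [read_annotations()].
#' @return `chains` with an added list-column `catalytic` of sorted 1-based
#'   integer positions (empty integer vector for unannotated chains).
#' @export
attach_annotations <- function(chains, annotations) {
  unknown <- setdiff(annotations$chain_id, chains$chain_id)
  if (length(unknown) > 0L) {
    stop_validation(sprintf("annotations reference unknown chain(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  ann_split <- split(annotations, annotations$chain_id)
  chains$catalytic <- lapply(seq_len(nrow(chains)), function(i) {
    a <- ann_split[[chains$chain_id[i]]]
    if (is.null(a)) return(integer())
    len <- nchar(chains$sequence[i])
    bad <- a$position < 1L | a$position > len
    if (any(bad)) {
      j <- which(bad)[1L]
      stop_validation(sprintf(
        "annotation out of range: chain %s position %d (sequence length %d)",
        a$chain_id[j], a$position[j], len))
    }
    found <- substring(chains$sequence[i], a$position, a$position)
    mism <- found != a$residue
    if (any(mism)) {
      j <- which(mism)[1L]
      warning(sprintf(
        "chain %s position %d: annotated residue %s but sequence has %s",
        a$chain_id[j], a$position[j], a$residue[j], found[j]), call. = FALSE)
    }
    sort(unique(a$position))
  })
  chains
}

# Locate the PSSM header line carrying two 20-letter column blocks and
# return the residue order of each block.
parse_pssm_header <- function(lines) {
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 40L && all(toks %in% AA_ORDER)) {
      return(list(line = i,
                  logodds_order = toks[1:20],
                  wop_order = toks[21:40]))
    }
  }
  stop_format("no PSI-BLAST profile header with two 20-residue column blocks found")
}

#' Read the weighted-observed-percentage block of a PSI-BLAST ASCII profile
#'
#' Parses the ASCII matrix dialect produced by PSI-BLAST (one row per
#' residue carrying 20 log-odds columns followed by 20 weighted observed
#' percentage columns).  Only the percentage block is kept; its columns are
#' remapped to the canonical alphabet order of [aa_alphabet()] if the file
#' uses a different order.
#'
#' @param path Path to the profile file.
#' @return An L x 20 numeric matrix of non-negative percentages (canonical
#'   column order), with the residue letters of the profile rows in
#'   attribute `"residues"`.
#' @export
read_wop_pssm <- function(path) {
  check_file_exists(path)
  lines <- readLines(path)
  hdr <- parse_pssm_header(lines)
  rows <- list()
  residues <- character()
  for (i in seq((hdr$line + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    toks <- strsplit(ln, "\\s+")[[1]]
    # data rows start "<index> <residue-letter> <numbers...>"
    if (is.na(suppressWarnings(as.integer(toks[1]))) || nchar(toks[2]) != 1L) break
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(vals) < 40L || anyNA(vals[1:40])) {
      stop_format(sprintf("unparseable profile row at line %d of %s", i, path))
    }
    idx <- as.integer(toks[1])
    if (idx != length(rows) + 1L) {
      stop_format(sprintf("non-consecutive row index %d at line %d of %s",
                          idx, i, path))
    }
    rows[[length(rows) + 1L]] <- vals[21:40]
    residues <- c(residues, toks[2])
  }
  if (length(rows) == 0L) stop_format(sprintf("profile %s has no data rows", path))
  wop <- do.call(rbind, rows)
  colnames(wop) <- hdr$wop_order
  wop <- wop[, AA_ORDER, drop = FALSE]
  if (any(wop < 0)) stop_format(sprintf("negative percentage in profile %s", path))
  attr(wop, "residues") <- residues
  wop
}

#' Write a weighted-observed-percentage matrix as a PSI-BLAST-style profile
#'
#' Emits the ASCII dialect read back by [read_wop_pssm()]: a header with
#' two 20-letter column blocks and, per residue, 20 log-odds columns
#' (written as zeros; only the percentage block is meaningful here)
#' followed by the 20 percentage columns.
#'
#' @param wop L x 20 non-negative matrix in canonical column order.
#' @param residues Character vector of length L of residue letters.
#' @param path Output path.
#' @param column_order Residue order used for the emitted percentage block;
#'   defaults to the canonical order.
#' @return `path`, invisibly.
#' @export
write_wop_pssm <- function(wop, residues, path, column_order = aa_alphabet()) {
  stopifnot(ncol(wop) == 20L, nrow(wop) == length(residues))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped matches",
    "",
    paste0("           ",
           paste(sprintf("%3s", c(AA_ORDER, column_order)), collapse = " "))
  ), con)
  perm <- match(column_order, AA_ORDER)
  for (i in seq_along(residues)) {
    writeLines(sprintf("%5d %s  %s  %s  %.2f %.2f",
                       i, residues[i],
                       paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                       paste(sprintf("%6.2f", wop[i, perm]), collapse = " "),
                       0, 1), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read PSIPRED `.ss2` secondary-structure probabilities
#'
#' Parses the PSIPRED VFORMAT (per residue: index, letter, predicted state,
#' then the coil, helix and strand probabilities in that order) and stores
#' the probabilities in (H, E, C) order.
#'
#' @param path Path to a `.ss2` file.
#' @return An L x 3 matrix with columns `H`, `E`, `C` and the residue
#'   letters in attribute `"residues"`.
#' @export
read_ss2 <- function(path) {
  check_file_exists(path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\\s+")
  bad <- vapply(rows, length, integer(1L)) != 6L
  if (any(bad)) {
    stop_format(sprintf("malformed .ss2 row in %s: '%s'",
                        path, lines[which(bad)[1L]]))
  }
  residues <- vapply(rows, `[[`, character(1L), 2L)
  num <- t(vapply(rows, function(r) suppressWarnings(as.numeric(r[4:6])),
                  numeric(3L)))
  if (anyNA(num)) stop_format(sprintf("non-numeric probability in %s", path))
  # file columns are (C, H, E); store (H, E, C)
  probs <- num[, c(2L, 3L, 1L), drop = FALSE]
  colnames(probs) <- c("H", "E", "C")
  attr(probs, "residues") <- residues
  probs
}

#' @rdname read_ss2
#' @param probs L x 3 matrix in (H, E, C) column order.
#' @param residues Residue letters, length L.
#' @export
write_ss2 <- function(probs, residues, path) {
  stopifnot(ncol(probs) == 3L, nrow(probs) == length(residues))
  state <- c("H", "E", "C")[max.col(probs, ties.method = "last")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", ""), con)
  # emit in file order (C, H, E)
  writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                     seq_along(residues), residues, state,
                     probs[, "C"], probs[, "H"], probs[, "E"]), con)
  invisible(path)
}

read_track_tsv <- function(path, value_col) {
  check_file_exists(path)
  df <- utils::read.delim(path)
  need <- c("position", "residue", value_col)
  if (!all(need %in% names(df))) {
    stop_format(sprintf("%s must have columns %s", path,
                        paste(need, collapse = ", ")))
  }
  if (!is.numeric(df[[value_col]])) {
    stop_format(sprintf("non-numeric %s value in %s", value_col, path))
  }
  df <- df[order(df$position), ]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop_format(sprintf("positions in %s are not consecutive from 1", path))
  }
  structure(df[[value_col]], residues = as.character(df$residue))
}

#' Read a per-residue solvent-accessibility track
#'
#' Reads a TSV with columns `position`, `residue`, `asa`.  Real-valued
#' accessibilities are binarised at `threshold` (exposed = 1); files whose
#' values are already all 0/1 pass through unchanged.
#'
#' @param path Path to the TSV file.
#' @param threshold Relative-accessibility cutoff for calling a residue
#'   exposed; default 5.0.
#' @return Integer vector of 0/1 with residue letters in attribute
#'   `"residues"`.
#' @export
read_asa <- function(path, threshold = 5) {
  vals <- read_track_tsv(path, "asa")
  res <- attr(vals, "residues")
  out <- if (all(vals %in% c(0, 1))) as.integer(vals) else as.integer(vals >= threshold)
  structure(out, residues = res)
}

#' Read a per-residue Consurf conservation track
#'
#' Reads a TSV with columns `position`, `residue`, `score`.  Scores are
#' kept as arbitrary finite reals; any normalisation happens at encoding
#' time.
#'
#' @param path Path to the TSV file.
#' @return Numeric vector with residue letters in attribute `"residues"`.
#' @export
read_consurf <- function(path) {
  vals <- read_track_tsv(path, "score")
  if (any(!is.finite(vals))) stop_format(sprintf("non-finite score in %s", path))
  vals
}

write_track_tsv <- function(values, residues, path, value_col) {
  df <- data.frame(position = seq_along(values), residue = residues,
                   value = values)
  names(df)[3] <- value_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_asa
#' @param values Numeric accessibility values, length L.
#' @param residues Residue letters, length L.
#' @export
write_asa <- function(values, residues, path) {
  write_track_tsv(values, residues, path, "asa")
}

#' @rdname read_consurf
#' @param values Numeric conservation scores, length L.
#' @param residues Residue letters, length L.
#' @export
write_consurf <- function(values, residues, path) {
  write_track_tsv(values, residues, path, "score")
}

MODEL_FORMAT_VERSION <- 1L

#' Save or load a fitted model
#'
#' Models are serialised as versioned JSON with full-precision decimal
#' encoding of all numeric fields, so `load_model(save_model(m))`
#' reproduces weights, intercept, lambda, window size, feature layout and
#' operating threshold exactly.
#'
#' @param model A `catsite_model` from [fit_l1logreg()].
#' @param path File path for the JSON model.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `catsite_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "catsite_model"))
  payload <- list(
    format = "catsite_model",
    version = MODEL_FORMAT_VERSION,
    window = model$layout$window,
    channels = model$layout$channels,
    slots = model$layout$slots,
    lambda = model$lambda,
    weights = unname(model$w),
    intercept = model$v,
    threshold = model$threshold
  )
  # I(17) significant digits: exact decimal round-trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  check_file_exists(path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop_format(sprintf("cannot parse model file %s: %s",
                                            path, conditionMessage(e)))
                      })
  if (!identical(payload$format, "catsite_model")) {
    stop_format(sprintf("%s is not a catsite model file", path))
  }
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION)) {
    stop_format(sprintf("unsupported model file version %s (expected %d)",
                        payload$version, MODEL_FORMAT_VERSION))
  }
  layout <- window_layout(payload$window, channels = payload$channels)
  if (!identical(layout$slots, payload$slots)) {
    stop_format(sprintf("feature layout in %s does not match its declared window/channels", path))
  }
  if (length(payload$weights) != layout$dim) {
    stop_format(sprintf("model file %s is truncated or corrupt (expected %d weights, found %d)",
                        path, layout$dim, length(payload$weights)))
  }
  new_catsite_model(w = stats::setNames(as.numeric(payload$weights), layout$slots),
                    v = as.numeric(payload$intercept),
                    lambda = as.numeric(payload$lambda),
                    layout = layout,
                    threshold = as.numeric(payload$threshold))
}
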