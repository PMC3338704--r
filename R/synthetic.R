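#' Specification for a synthetic chain set
#'
#' Describes a synthetic dataset with a planted catalytic signal: chain
#' count, length range, catalytic sites per chain, signal strength and
#' which feature channels carry the signal.  The generator emulates the
#' shapes of the real inputs (PSI-BLAST percentage profiles, PSIPRED
#' probabilities, binary accessibility, conservation scores); it does not
#' emulate alignment depth or phylogenetic correlation between chains.
#'
#' @param n_chains Number of chains.
#' @param length_range Integer (min, max) chain length; minimum 30.
#' @param catalytic_per_chain Catalytic residues per chain.
#' @param signal Signal strength sigma in \[0, 1\]; 0 plants no signal
#'   (labels independent of features), 1 makes catalytic profile columns
#'   exactly one-hot.
#' @param seed RNG seed (mandatory; generation is fully reproducible).
#' @param signal_channels Channels into which signal is planted; any of
#'   `"RT"`/`"OP"` (catalytic residues drawn from polar/charged types),
#'   `"WOP"` (concentrated profile columns, driving JSD/RVD/VJSD),
#'   `"SS"` (coil boost), `"ASA"` (forced exposure), `"Consurf"`
#'   (shifted conservation).
#' @return A `catsite_synth_spec` list.
#' @export
synth_spec <- function(n_chains = 50L, length_range = c(60L, 120L),
                       catalytic_per_chain = 3L, signal = 0.8, seed,
                       signal_channels = c("RT", "OP", "WOP", "SS", "ASA",
                                           "Consurf")) {
  if (missing(seed)) stop_validation("a seed is mandatory for synthetic data")
  if (length_range[1] < 30L) stop_validation("minimum chain length is 30")
  if (catalytic_per_chain < 1L) stop_validation("at least one catalytic residue per chain")
  if (signal < 0 || signal > 1) stop_validation("signal must lie in [0, 1]")
  if (catalytic_per_chain >= length_range[1]) {
    stop_validation("more catalytic sites than the shortest allowed chain")
  }
  structure(list(n_chains = as.integer(n_chains),
                 length_range = as.integer(length_range),
                 catalytic_per_chain = as.integer(catalytic_per_chain),
                 signal = signal, seed = as.integer(seed),
                 signal_channels = signal_channels),
            class = "catsite_synth_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) {
    # numerically degenerate draw: fall back to the mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

generate_one_chain <- function(chain_id, spec) {
  sig <- spec$signal
  on <- function(ch) ch %in% spec$signal_channels
  q <- AA_BACKGROUND
  L <- spec$length_range[1] +
    sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L) - 1L
  catalytic <- sort(sample(seq_len(L), spec$catalytic_per_chain))
  res <- sample(AA_ORDER, L, replace = TRUE, prob = q)
  # catalytic residues lean polar/charged (the residue-type signal);
  # the redraw probability is sigma itself so that sigma = 0 leaves the
  # labels independent of every feature channel
  if (on("RT") || on("OP")) {
    polar_charged <- union(AA_CLASSES$Polar, AA_CLASSES$Charged)
    for (p in catalytic) {
      if (stats::runif(1) < sig) {
        qpc <- q[polar_charged] / sum(q[polar_charged])
        res[p] <- sample(polar_charged, 1L, prob = qpc)
      }
    }
  }
  # profile: mild Dirichlet noise about background off-site; concentrated
  # towards the true residue at catalytic sites
  wop <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ORDER))
  for (i in seq_len(L)) {
    target <- if (i %in% catalytic && on("WOP")) {
      onehot <- stats::setNames(numeric(20), AA_ORDER)
      onehot[res[i]] <- 1
      (1 - sig) * q + sig * onehot
    } else q
    wop[i, ] <- 100 * rdirichlet1(50 * target)
  }
  # secondary structure: catalytic sites drift towards coil
  ss_base <- c(H = 0.35, E = 0.25, C = 0.40)
  ss <- matrix(0, nrow = L, ncol = 3L, dimnames = list(NULL, c("H", "E", "C")))
  for (i in seq_len(L)) {
    target <- if (i %in% catalytic && on("SS")) {
      (1 - sig) * ss_base + sig * c(H = 0, E = 0, C = 1)
    } else ss_base
    ss[i, ] <- rdirichlet1(30 * pmax(target, 1e-6))
  }
  # accessibility: catalytic sites exposed with probability 1/2 + sigma/2
  p_exposed <- rep(0.5, L)
  if (on("ASA")) p_exposed[catalytic] <- 0.5 + sig / 2
  exposed <- stats::runif(L) < p_exposed
  # real-valued accessibilities so the reader's binarisation is exercised
  asa_raw <- ifelse(exposed, stats::runif(L, 10, 60), stats::runif(L, 0, 4))
  # conservation: unit-variance noise, catalytic sites shifted +2 sd
  consurf <- stats::rnorm(L)
  if (on("Consurf")) consurf[catalytic] <- consurf[catalytic] + 2 * sig
  list(chain_id = chain_id,
       sequence = paste(res, collapse = ""),
       catalytic = catalytic,
       wop = structure(wop, residues = res),
       ss = structure(ss, residues = res),
       asa_raw = asa_raw,
       asa = as.integer(exposed),
       consurf = consurf)
}

#' Generate a synthetic chain set in memory
#'
#' Draws every chain of the specification: sequences from the background
#' residue distribution, catalytic positions uniformly, and all four
#' per-residue tracks with the planted signal described in
#' [synth_spec()].  Identical specs (including seed) give identical
#' output.
#'
#' @param spec A `catsite_synth_spec`.
#' @return A tibble with columns `chain_id`, `sequence` and list-columns
#'   `catalytic`, `wop`, `ss`, `asa`, `asa_raw`, `consurf`.
#' @export
generate_chains <- function(spec) {
  stopifnot(inherits(spec, "catsite_synth_spec"))
  with_rng(spec$seed, {
    ids <- sprintf("synth%03d", seq_len(spec$n_chains))
    rows <- lapply(ids, generate_one_chain, spec = spec)
    tibble::tibble(
      chain_id = ids,
      sequence = vapply(rows, `[[`, character(1L), "sequence"),
      catalytic = lapply(rows, `[[`, "catalytic"),
      wop = lapply(rows, `[[`, "wop"),
      ss = lapply(rows, `[[`, "ss"),
      asa = lapply(rows, `[[`, "asa"),
      asa_raw = lapply(rows, `[[`, "asa_raw"),
      consurf = lapply(rows, `[[`, "consurf")
    )
  })
}

#' Write a synthetic chain set as a file-backed dataset
#'
#' Emits every external file format the pipeline reads: one FASTA, one
#' annotation TSV, and per chain a PSI-BLAST-style profile, a PSIPRED
#' `.ss2` file, a real-valued accessibility TSV and a Consurf TSV, plus a
#' `manifest.json` recording the spec, seed and relative paths.  Every
#' file parses back through the package's readers.
#'
#' @param spec A `catsite_synth_spec`, or a chain tibble from
#'   [generate_chains()] (then `seed`/spec metadata in the manifest come
#'   from `attr(chains, "spec")` if present).
#' @param dir Output directory (created if missing).
#' @return The manifest as a list (invisibly written to
#'   `dir/manifest.json`).
#' @export
write_dataset <- function(spec, dir) {
  chains <- if (inherits(spec, "catsite_synth_spec")) generate_chains(spec) else spec
  meta <- if (inherits(spec, "catsite_synth_spec")) unclass(spec) else
    list(n_chains = nrow(chains))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_io(sprintf("cannot create directory %s", dir))
  write_fasta(chains, file.path(dir, "chains.fasta"))
  ann <- dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
    pos <- chains$catalytic[[i]]
    tibble::tibble(chain_id = chains$chain_id[i], position = pos,
                   residue = substring(chains$sequence[i], pos, pos))
  }))
  write_annotations(ann, file.path(dir, "annotations.tsv"))
  files <- list(fasta = "chains.fasta", annotations = "annotations.tsv",
                profiles = list(), ss2 = list(), asa = list(),
                consurf = list())
  for (i in seq_len(nrow(chains))) {
    id <- chains$chain_id[i]
    res <- split_residues(chains$sequence[i])
    f_prof <- paste0(id, ".pssm")
    f_ss2 <- paste0(id, ".ss2")
    f_asa <- paste0(id, ".asa.tsv")
    f_cons <- paste0(id, ".consurf.tsv")
    write_wop_pssm(chains$wop[[i]], res, file.path(dir, f_prof))
    write_ss2(chains$ss[[i]], res, file.path(dir, f_ss2))
    asa_vals <- if ("asa_raw" %in% names(chains)) chains$asa_raw[[i]] else chains$asa[[i]]
    write_asa(asa_vals, res, file.path(dir, f_asa))
    write_consurf(chains$consurf[[i]], res, file.path(dir, f_cons))
    files$profiles[[id]] <- f_prof
    files$ss2[[id]] <- f_ss2
    files$asa[[id]] <- f_asa
    files$consurf[[id]] <- f_cons
  }
  manifest <- list(format = "catsite_dataset", version = 1L, spec = meta,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a file-backed dataset
#'
#' Reads a directory written by [write_dataset()] (or any directory with a
#' conforming `manifest.json`) back into a chain tibble, validating that
#' every per-residue track matches its chain's sequence length.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @param asa_threshold Binarisation cutoff passed to [read_asa()].
#' @return A tibble with columns `chain_id`, `sequence` and list-columns
#'   `catalytic`, `wop`, `ss`, `asa`, `consurf`.
#' @export
load_dataset <- function(dir, asa_threshold = 5) {
  manifest_path <- file.path(dir, "manifest.json")
  check_file_exists(manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "catsite_dataset")) {
    stop_format(sprintf("%s is not a catsite dataset manifest", manifest_path))
  }
  chains <- read_fasta(file.path(dir, manifest$files$fasta))
  ann <- read_annotations(file.path(dir, manifest$files$annotations))
  chains <- attach_annotations(chains, ann)
  get_track <- function(kind, reader, ...) {
    lapply(chains$chain_id, function(id) {
      rel <- manifest$files[[kind]][[id]]
      if (is.null(rel)) stop_io(sprintf("manifest lists no %s file for chain %s", kind, id))
      reader(file.path(dir, rel), ...)
    })
  }
  chains$wop <- get_track("profiles", read_wop_pssm)
  chains$ss <- get_track("ss2", read_ss2)
  chains$asa <- get_track("asa", read_asa, threshold = asa_threshold)
  chains$consurf <- get_track("consurf", read_consurf)
  for (i in seq_len(nrow(chains))) {
    L <- nchar(chains$sequence[i])
    lens <- c(wop = nrow(chains$wop[[i]]), ss = nrow(chains$ss[[i]]),
              asa = length(chains$asa[[i]]), consurf = length(chains$consurf[[i]]))
    bad <- lens != L
    if (any(bad)) {
      stop_validation(sprintf(
        "chain %s: %s track has length %d but sequence has length %d",
        chains$chain_id[i], names(lens)[bad][1], lens[bad][1], L))
    }
  }
  chains
}
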