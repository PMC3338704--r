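# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package route through this so results are
# reproducible from (inputs, seed) and never disturb the session RNG.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

abort_catsite <- function(msg, class) {
  rlang::abort(msg, class = c(class, "catsite_error"))
}

stop_format <- function(msg) abort_catsite(msg, "catsite_format_error")
stop_validation <- function(msg) abort_catsite(msg, "catsite_validation_error")
stop_io <- function(msg) abort_catsite(msg, "catsite_io_error")

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("file not found: %s", path))
  }
  invisible(path)
}
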