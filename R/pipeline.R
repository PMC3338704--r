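#' Train a catalytic-residue model on a chain set
#'
#' Builds the 6:1 subsampled training set, fits the L1-regularised
#' logistic model at the given (window, lambda), and sets the model's
#' operating threshold to the maximal-F-measure point of the training
#' sweep.
#'
#' @inheritParams cross_validate
#' @param window Window half-width; default 6 (the tuned default).
#' @param lambda Penalty strength; default 0.01.
#' @return A `catsite_model` with its operating `threshold` set.
#' @export
train_model <- function(chains, window = 6L, lambda = 0.01, ratio = 6L,
                        seed = 1L, channels = CHANNELS, tol = 1e-8,
                        max_iter = 100000L) {
  features <- chain_features(chains)
  selection <- training_selection(chains, ratio,
                                  seed = derive_seed(seed, "subsample"))
  layout <- window_layout(window, channels)
  dataset <- build_dataset(features, selection, layout)
  model <- fit_l1logreg(dataset, lambda, tol = tol, max_iter = max_iter)
  scores <- predict_scores(model, dataset)
  op <- best_operating_point(rank_sweep(scores, dataset$y, dataset$groups,
                                        dataset$positions))
  model$threshold <- op$score
  model
}

#' Score every residue of every chain
#'
#' Applies a fitted model to all residues, emitting one row per residue
#' with its predicted catalytic probability and the binary call at the
#' model's operating threshold.
#'
#' @param model A `catsite_model`.
#' @param chains Chain tibble with the track list-columns (a `catalytic`
#'   column is not required for prediction).
#' @param features Optional precomputed [chain_features()] list.
#' @return A tibble with columns `chain_id`, `position`, `residue`,
#'   `score`, `call` (1 iff `score >= model$threshold`).
#' @export
predict_chains <- function(model, chains, features = NULL) {
  features <- features %||% chain_features(chains)
  selected <- dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
    tibble::tibble(chain_id = chains$chain_id[i],
                   position = seq_len(nchar(chains$sequence[i])))
  }))
  dataset <- build_dataset(features, selected, model$layout)
  scores <- predict_scores(model, dataset)
  dplyr::mutate(
    selected,
    residue = vapply(seq_len(nrow(selected)), function(i) {
      substring(chains$sequence[match(selected$chain_id[i], chains$chain_id)],
                selected$position[i], selected$position[i])
    }, character(1L)),
    score = scores,
    call = as.integer(scores >= model$threshold)
  )[c("chain_id", "position", "residue", "score", "call")]
}

#' Evaluate whole-chain predictions against annotations
#'
#' Labels every predicted residue by the annotation table (+1 if the
#' (chain, position) pair is annotated catalytic, -1 otherwise) and runs
#' the full PR/ROC evaluation over all residues.
#'
#' @param predictions A tibble from [predict_chains()].
#' @param annotations A tibble with columns `chain_id`, `position` (e.g.
#'   from [read_annotations()]).
#' @return A `catsite_eval`.
#' @export
evaluate_predictions <- function(predictions, annotations) {
  key <- paste(annotations$chain_id, annotations$position)
  labels <- ifelse(paste(predictions$chain_id, predictions$position) %in% key,
                   1, -1)
  evaluate_scores(predictions$score, labels, predictions$chain_id,
                  predictions$position)
}
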