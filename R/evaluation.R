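#' Subsample non-catalytic residues of one chain
#'
#' Selects, uniformly at random, `ratio` non-catalytic residues per
#' catalytic residue of the chain (fewer when the chain runs out of
#' non-catalytic positions).  Chains without catalytic residues contribute
#' nothing.
#'
#' @param length Chain length.
#' @param catalytic Integer vector of 1-based catalytic positions.
#' @param ratio Negatives per positive; default 6.
#' @param seed RNG seed making the selection reproducible.
#' @return Sorted integer vector of selected non-catalytic positions.
#' @export
subsample_negatives <- function(length, catalytic, ratio = 6L, seed) {
  if (ratio < 1L) stop_validation("ratio must be >= 1")
  if (base::length(catalytic) == 0L) return(integer())
  pool <- setdiff(seq_len(length), catalytic)
  n_take <- min(ratio * base::length(catalytic), base::length(pool))
  with_rng(seed, sort(pool[sample.int(base::length(pool), n_take)]))
}

#' Build the labelled training selection for a chain set
#'
#' Takes every catalytic residue as a positive and, per chain,
#' `ratio` randomly chosen non-catalytic residues per positive as
#' negatives.
#'
#' @param chains A tibble with columns `chain_id`, `sequence` and
#'   list-column `catalytic`.
#' @param ratio Negatives per positive; default 6.
#' @param seed RNG seed.
#' @return A tibble with columns `chain_id`, `position`, `label` (+1/-1).
#' @export
training_selection <- function(chains, ratio = 6L, seed = 1L) {
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    cat_pos <- chains$catalytic[[i]]
    if (length(cat_pos) == 0L) return(NULL)
    neg <- subsample_negatives(nchar(chains$sequence[i]), cat_pos, ratio,
                               seed = derive_seed(seed, chains$chain_id[i]))
    tibble::tibble(chain_id = chains$chain_id[i],
                   position = c(cat_pos, neg),
                   label = rep(c(1, -1), c(length(cat_pos), length(neg))))
  })
  dplyr::bind_rows(rows)
}

#' Group-aware fold assignment
#'
#' Shuffles the chains with the given seed and deals them round-robin into
#' `k` folds, so every residue of a chain shares its chain's fold and fold
#' sizes differ by at most one chain.
#'
#' @param chain_ids Character vector of chain identifiers.
#' @param k Number of folds; default 10.
#' @param seed RNG seed.
#' @return A tibble with columns `chain_id` and `fold` (1-based).
#' @export
make_folds <- function(chain_ids, k = 10L, seed = 1L) {
  n <- length(chain_ids)
  if (k > n) stop_validation(sprintf("cannot make %d folds from %d chains", k, n))
  shuffled <- with_rng(seed, sample(chain_ids))
  tibble::tibble(chain_id = shuffled,
                 fold = rep_len(seq_len(k), n))
}

#' Rank-threshold sweep over scored sites
#'
#' Sorts all sites by decreasing score (ties broken by the stable order of
#' `chain_id` then `position`, or input order when absent) and grows the
#' predicted set one site at a time, recording the confusion counts,
#' precision, recall, false-positive rate and F-measure after every
#' prefix.
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels in \{+1, -1\}; both classes must be present.
#' @param chain_id,position Optional tie-break keys.
#' @return A tibble with one row per prefix and columns `rank`, `score`,
#'   `label`, `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `fpr`, `f`.
#' @export
rank_sweep <- function(scores, labels, chain_id = NULL, position = NULL) {
  check_labels(labels, both_classes = TRUE)
  n <- length(scores)
  ord <- if (is.null(chain_id)) {
    order(-scores, seq_len(n), method = "radix")
  } else {
    order(-scores, chain_id, position, method = "radix")
  }
  lab <- labels[ord]
  n_pos <- sum(lab == 1)
  n_neg <- n - n_pos
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == -1)
  fn <- n_pos - tp
  tn <- n_neg - fp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  fpr <- fp / n_neg
  f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  tibble::tibble(rank = seq_len(n), score = scores[ord], label = lab,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, fpr = fpr, f = f)
}

#' Precision-recall and ROC point sequences
#'
#' @inheritParams rank_sweep
#' @return A list with elements `pr` (tibble of `recall`, `precision`) and
#'   `roc` (tibble of `fpr`, `recall`), one row per sweep prefix.
#' @export
pr_roc_points <- function(scores, labels, chain_id = NULL, position = NULL) {
  sweep <- rank_sweep(scores, labels, chain_id, position)
  list(pr = sweep[c("recall", "precision")],
       roc = sweep[c("fpr", "recall")])
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision induced by the one-site-at-a-time sweep:
#' the mean, over positives, of the precision at each positive's rank.
#' A trapezoidal PR area is available via `method`.
#'
#' @param sweep A tibble from [rank_sweep()].
#' @param method `"step"` (average precision, default) or `"trapezoid"`.
#' @return A number in \[0, 1\].
#' @export
aupr <- function(sweep, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  if (method == "step") {
    sum(sweep$precision[sweep$label == 1]) / sum(sweep$label == 1)
  } else {
    r <- c(0, sweep$recall)
    p <- c(sweep$precision[1], sweep$precision)
    sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  }
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the rank sweep with tied scores collapsed into
#' single steps, which equals the Mann-Whitney pair-ordering statistic
#' with ties counted one half.
#'
#' @param sweep A tibble from [rank_sweep()].
#' @return A number in \[0, 1\].
#' @export
auc <- function(sweep) {
  # collapse tie blocks so a tied positive/negative pair contributes 1/2
  last_of_block <- c(sweep$score[-1] != sweep$score[-nrow(sweep)], TRUE)
  r <- c(0, sweep$recall[last_of_block])
  x <- c(0, sweep$fpr[last_of_block])
  sum(diff(x) * (r[-1] + r[-length(r)]) / 2)
}

#' Maximal F-measure operating point
#'
#' Finds the sweep prefix with the largest F-measure (earliest prefix on
#' ties); its score is the model's operating threshold and its precision,
#' recall and FPR are the headline point estimates.
#'
#' @param sweep A tibble from [rank_sweep()].
#' @return One row of the sweep.
#' @export
best_operating_point <- function(sweep) {
  if (nrow(sweep) == 0L) stop_validation("empty sweep")
  sweep[which.max(sweep$f), ]
}

#' Evaluate scored sites
#'
#' Builds the full rank sweep and summarises it: AUPR, AUC, and the
#' maximal-F-measure operating point with its confusion counts.
#'
#' @inheritParams rank_sweep
#' @return A `catsite_eval` with fields `sweep`, `aupr`, `auc`,
#'   `operating_point`, `n`, `n_pos`.
#' @export
evaluate_scores <- function(scores, labels, chain_id = NULL, position = NULL) {
  sweep <- rank_sweep(scores, labels, chain_id, position)
  structure(list(sweep = sweep,
                 aupr = aupr(sweep),
                 auc = auc(sweep),
                 operating_point = best_operating_point(sweep),
                 n = nrow(sweep),
                 n_pos = sum(sweep$label == 1)),
            class = "catsite_eval")
}

#' @export
print.catsite_eval <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("<catsite_eval> %d sites (%d positive)\n", x$n, x$n_pos))
  cat(sprintf("  AUPR %.4f  AUC %.4f\n", x$aupr, x$auc))
  cat(sprintf("  max-F point: F %.4f  P %.4f  R %.4f  FPR %.4f (threshold %.4g)\n",
              op$f, op$precision, op$recall, op$fpr, op$score))
  invisible(x)
}

#' @rdname evaluate_scores
#' @param x A `catsite_eval`.
#' @param ... Unused.
#' @export
glance.catsite_eval <- function(x, ...) {
  op <- x$operating_point
  tibble::tibble(n = x$n, n_pos = x$n_pos, aupr = x$aupr, auc = x$auc,
                 threshold = op$score, precision = op$precision,
                 recall = op$recall, fpr = op$fpr, f = op$f,
                 tp = op$tp, fp = op$fp, tn = op$tn, fn = op$fn)
}

#' @rdname evaluate_scores
#' @export
tidy.catsite_eval <- function(x, ...) x$sweep

#' Plot PR and ROC curves of an evaluation
#'
#' @param object A `catsite_eval`.
#' @param ... Unused.
#' @return A ggplot object with the precision-recall and ROC curves as
#'   facets; the maximal-F operating point is marked.
#' @export
autoplot.catsite_eval <- function(object, ...) {
  sweep <- object$sweep
  op <- object$operating_point
  df <- dplyr::bind_rows(
    tibble::tibble(curve = "Precision-Recall", x = sweep$recall, y = sweep$precision),
    tibble::tibble(curve = "ROC", x = sweep$fpr, y = sweep$recall)
  )
  pts <- dplyr::bind_rows(
    tibble::tibble(curve = "Precision-Recall", x = op$recall, y = op$precision),
    tibble::tibble(curve = "ROC", x = op$fpr, y = op$recall)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = pts, colour = "red") +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(
      x = "Recall / FPR", y = "Precision / Recall",
      title = sprintf("AUPR %.4f, AUC %.4f (max-F point in red)",
                      object$aupr, object$auc)) +
    ggplot2::theme_minimal()
}

#' Build per-chain feature tables for a chain set
#'
#' @param chains A tibble with columns `chain_id`, `sequence` and
#'   list-columns `wop`, `ss`, `asa`, `consurf`.
#' @param background Background residue distribution.
#' @return Named list of `catsite_features`, one per chain.
#' @export
chain_features <- function(chains, background = aa_background()) {
  out <- lapply(seq_len(nrow(chains)), function(i) {
    build_feature_table(chains$chain_id[i], chains$sequence[i],
                        chains$wop[[i]], chains$ss[[i]], chains$asa[[i]],
                        chains$consurf[[i]], background = background)
  })
  stats::setNames(out, chains$chain_id)
}

# all-residue selection (for whole-chain prediction / full-universe eval)
full_selection <- function(chains) {
  dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
    L <- nchar(chains$sequence[i])
    tibble::tibble(chain_id = chains$chain_id[i], position = seq_len(L),
                   label = ifelse(seq_len(L) %in% chains$catalytic[[i]], 1, -1))
  }))
}

#' Group-aware k-fold cross-validation of the predictor
#'
#' Subsamples negatives at `ratio` per positive, assigns chains to folds,
#' and for every fold trains an L1-logistic model on the other folds'
#' rows and scores the held-out chains.  Held-out scores are pooled across
#' folds and one PR/ROC evaluation is computed on the pool.
#'
#' @param chains Chain tibble with list-columns `catalytic`, `wop`, `ss`,
#'   `asa`, `consurf`.
#' @param window Window half-width w (the window spans 2w + 1 residues).
#' @param lambda L1 penalty strength.
#' @param k Number of folds; default 10.
#' @param seed RNG seed controlling subsampling and fold assignment.
#' @param ratio Negatives subsampled per positive; default 6.
#' @param universe Score the held-out chains' subsampled rows
#'   (`"subsampled"`, the tuning mode) or all their residues (`"full"`).
#' @param channels Feature channels to use; default all eight.
#' @param tol,max_iter Solver controls passed to [fit_l1logreg()].
#' @param features Optional precomputed [chain_features()] list.
#' @param selection,folds Optional precomputed selection/fold tables
#'   (used by [grid_search()] to hold them fixed across cells).
#' @return A `catsite_cv`: list with `scores` (tibble of `chain_id`,
#'   `position`, `label`, `fold`, `score`) and `report` (a
#'   `catsite_eval`).
#' @export
cross_validate <- function(chains, window, lambda, k = 10L, seed = 1L,
                           ratio = 6L, universe = c("subsampled", "full"),
                           channels = CHANNELS, tol = 1e-8,
                           max_iter = 100000L, features = NULL,
                           selection = NULL, folds = NULL) {
  universe <- match.arg(universe)
  features <- features %||% chain_features(chains)
  selection <- selection %||%
    training_selection(chains, ratio, seed = derive_seed(seed, "subsample"))
  folds <- folds %||%
    make_folds(unique(selection$chain_id), k, seed = derive_seed(seed, "folds"))
  layout <- window_layout(window, channels)
  train_data <- build_dataset(features, selection, layout)
  fold_of <- stats::setNames(folds$fold, folds$chain_id)
  row_fold <- unname(fold_of[train_data$groups])
  test_selection <- if (universe == "subsampled") selection else
    dplyr::filter(full_selection(chains), .data$chain_id %in% folds$chain_id)
  test_fold <- unname(fold_of[test_selection$chain_id])
  pooled <- vector("list", k)
  for (f in sort(unique(folds$fold))) {
    tr <- row_fold != f
    y_tr <- train_data$y[tr]
    if (length(unique(y_tr)) < 2L) {
      stop_validation(sprintf("fold %d: training data contains a single class", f))
    }
    sub <- structure(list(X = train_data$X[tr, , drop = FALSE], y = y_tr,
                          groups = train_data$groups[tr],
                          positions = train_data$positions[tr],
                          layout = layout),
                     class = "catsite_dataset")
    model <- fit_l1logreg(sub, lambda, tol = tol, max_iter = max_iter)
    te <- test_selection[test_fold == f, , drop = FALSE]
    te_data <- build_dataset(features, te, layout)
    pooled[[f]] <- dplyr::mutate(te, fold = f,
                                 score = predict_scores(model, te_data))
  }
  scores <- dplyr::bind_rows(pooled)
  report <- evaluate_scores(scores$score, scores$label,
                            scores$chain_id, scores$position)
  structure(list(scores = scores, report = report, window = window,
                 lambda = lambda, k = k, seed = seed, universe = universe,
                 channels = channels),
            class = "catsite_cv")
}

#' @export
print.catsite_cv <- function(x, ...) {
  cat(sprintf("<catsite_cv> window %d, lambda %g, %d-fold (%s universe)\n",
              x$window, x$lambda, x$k, x$universe))
  print(x$report)
  invisible(x)
}

#' Grid search over window size and penalty strength
#'
#' Runs [cross_validate()] at every (window, lambda) pair of the grid and
#' picks the cell with the highest pooled AUPR (ties broken towards the
#' smaller window, then the smaller lambda).  The negative subsample and
#' the fold assignment are drawn once from `seed` and held fixed across
#' cells, so cells differ only in (window, lambda).
#'
#' @inheritParams cross_validate
#' @param windows Window half-widths to scan; default 0 to 10.
#' @param lambdas Penalty values to scan; default 0.001 to 0.02 in steps
#'   of 0.001 (220 cells with the default windows).
#' @param verbose Log each cell's result to standard error.
#' @return A `catsite_grid`: list with `table` (tibble of `window`,
#'   `lambda`, `aupr`, `auc`) and `best` (one-row tibble).
#' @export
grid_search <- function(chains, windows = 0:10,
                        lambdas = seq(0.001, 0.02, by = 0.001),
                        k = 10L, seed = 1L, ratio = 6L,
                        channels = CHANNELS, tol = 1e-8,
                        max_iter = 100000L, verbose = FALSE) {
  if (length(windows) == 0L || length(lambdas) == 0L) {
    stop_validation("empty grid")
  }
  features <- chain_features(chains)
  selection <- training_selection(chains, ratio, seed = derive_seed(seed, "subsample"))
  folds <- make_folds(unique(selection$chain_id), k,
                      seed = derive_seed(seed, "folds"))
  rows <- list()
  for (w in windows) {
    for (lam in lambdas) {
      cv <- cross_validate(chains, w, lam, k = k, seed = seed, ratio = ratio,
                           channels = channels, tol = tol,
                           max_iter = max_iter, features = features,
                           selection = selection, folds = folds)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        window = w, lambda = lam, aupr = cv$report$aupr, auc = cv$report$auc)
      if (verbose) {
        message(sprintf("[grid] window=%d lambda=%.3f AUPR=%.4f AUC=%.4f",
                        w, lam, cv$report$aupr, cv$report$auc))
      }
    }
  }
  table <- dplyr::bind_rows(rows)
  best <- dplyr::arrange(table, dplyr::desc(.data$aupr), .data$window,
                         .data$lambda)[1, ]
  structure(list(table = table, best = best, k = k, seed = seed,
                 ratio = ratio, channels = channels),
            class = "catsite_grid")
}

#' @export
print.catsite_grid <- function(x, ...) {
  cat(sprintf("<catsite_grid> %d cells; best: window %d, lambda %g (AUPR %.4f, AUC %.4f)\n",
              nrow(x$table), x$best$window, x$best$lambda, x$best$aupr,
              x$best$auc))
  invisible(x)
}

#' @rdname grid_search
#' @param x A `catsite_grid`.
#' @param ... Unused.
#' @export
tidy.catsite_grid <- function(x, ...) x$table

#' Heatmap of grid-search AUPR
#'
#' @param object A `catsite_grid`.
#' @param ... Unused.
#' @return A ggplot tile plot of mean pooled AUPR over the grid.
#' @export
autoplot.catsite_grid <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$lambda), y = factor(.data$window),
                               fill = .data$aupr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, colour = "red") +
    ggplot2::labs(x = "lambda", y = "window half-width", fill = "AUPR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Leave-one-channel-out cross-validation
#'
#' Drops one of the eight feature channels, rebuilds the layout without
#' its slots, and reruns the pooled cross-validation, quantifying the
#' channel's contribution.
#'
#' @inheritParams cross_validate
#' @param channel Channel to remove (one of `"RT"`, `"OP"`, `"ACH"`,
#'   `"SS"`, `"ASA"`, `"JSD"`, `"VJSD"`, `"Consurf"`).
#' @return A `catsite_cv` fitted without the channel.
#' @export
ablate_channel <- function(chains, channel, window, lambda, k = 10L,
                           seed = 1L, ratio = 6L, tol = 1e-8,
                           max_iter = 100000L, features = NULL,
                           selection = NULL, folds = NULL) {
  if (!channel %in% CHANNELS) {
    stop_validation(sprintf("unknown channel '%s' (expected one of %s)",
                            channel, paste(CHANNELS, collapse = ", ")))
  }
  cross_validate(chains, window, lambda, k = k, seed = seed, ratio = ratio,
                 channels = setdiff(CHANNELS, channel), tol = tol,
                 max_iter = max_iter, features = features,
                 selection = selection, folds = folds)
}

#' Full leave-one-channel-out study
#'
#' Runs the pooled cross-validation once with all eight channels and once
#' per channel with that channel removed, mirroring the
#' feature-importance experiment.
#'
#' @inheritParams cross_validate
#' @return A tibble with one row per configuration (`"full"` plus
#'   `"no-<channel>"`) and columns `configuration`, `n_features`, `aupr`,
#'   `auc`, `precision`, `recall`.
#' @export
ablation_study <- function(chains, window, lambda, k = 10L, seed = 1L,
                           ratio = 6L, tol = 1e-8, max_iter = 100000L) {
  features <- chain_features(chains)
  selection <- training_selection(chains, ratio, seed = derive_seed(seed, "subsample"))
  folds <- make_folds(unique(selection$chain_id), k,
                      seed = derive_seed(seed, "folds"))
  one <- function(label, channels) {
    cv <- cross_validate(chains, window, lambda, k = k, seed = seed,
                         ratio = ratio, channels = channels, tol = tol,
                         max_iter = max_iter, features = features,
                         selection = selection, folds = folds)
    op <- cv$report$operating_point
    tibble::tibble(configuration = label,
                   n_features = window_layout(window, channels)$dim,
                   aupr = cv$report$aupr, auc = cv$report$auc,
                   precision = op$precision, recall = op$recall)
  }
  dplyr::bind_rows(c(
    list(one("full", CHANNELS)),
    lapply(CHANNELS, function(ch) one(paste0("no-", ch), setdiff(CHANNELS, ch)))
  ))
}
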