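# Numerically stable log(1 + exp(-m)) for arbitrary margins
log1pexp_neg <- function(m) {
  out <- numeric(length(m))
  pos <- m > 0
  out[pos] <- log1p(exp(-m[pos]))
  out[!pos] <- -m[!pos] + log1p(exp(m[!pos]))
  out
}

check_labels <- function(y, both_classes = FALSE) {
  if (!all(y %in% c(-1, 1))) stop_validation("labels must be +1 or -1")
  if (both_classes && length(unique(y)) < 2L) {
    stop_validation("both classes must be present")
  }
}

#' L1-regularised logistic objective
#'
#' The average logistic loss plus an L1 penalty on the weights (the
#' intercept is not penalised):
#' `(1/m) * sum_i log(1 + exp(-y_i (w'x_i + v))) + lambda * ||w||_1`.
#' Stable for margins up to +/- 1e4 and beyond.
#'
#' @param w Weight vector of length d.
#' @param v Intercept.
#' @param X N x d feature matrix.
#' @param y Labels in \{+1, -1\}.
#' @param lambda L1 penalty strength.
#' @return The objective value.
#' @export
logistic_objective <- function(w, v, X, y, lambda) {
  check_labels(y)
  margins <- y * (drop(X %*% w) + v)
  mean(log1pexp_neg(margins)) + lambda * sum(abs(w))
}

# gradient of the smooth part at (w, v): list(gw, gv)
logistic_gradient <- function(w, v, X, y) {
  margins <- y * (drop(X %*% w) + v)
  s <- -y * stats::plogis(-margins)   # -y * sigma(-margin)
  list(gw = drop(crossprod(X, s)) / length(y), gv = mean(s))
}

#' Smallest fully-sparsifying penalty
#'
#' The smallest `lambda` at which the all-zero weight vector (with its
#' optimal intercept `v* = log(m+/m-)`) minimises the L1-regularised
#' logistic objective: the largest coordinate of the loss gradient at
#' that point.
#'
#' @inheritParams logistic_objective
#' @return A single positive number.
#' @export
lambda_max <- function(X, y) {
  check_labels(y, both_classes = TRUE)
  v_star <- log(sum(y == 1) / sum(y == -1))
  g <- logistic_gradient(numeric(ncol(X)), v_star, X, y)
  max(abs(g$gw))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0) + 0  # +0 kills -0

# Largest eigenvalue of A'A / m for A = [X, 1], by power iteration
lipschitz_bound <- function(X) {
  m <- nrow(X)
  z <- rep(1, ncol(X) + 1L)
  z <- z / sqrt(sum(z^2))
  ev <- 0
  for (i in 1:100) {
    Az <- drop(X %*% z[-length(z)]) + z[length(z)]
    z2 <- c(drop(crossprod(X, Az)), sum(Az))
    ev_new <- sqrt(sum(z2^2))
    z <- z2 / ev_new
    if (abs(ev_new - ev) < 1e-10 * max(ev_new, 1)) break
    ev <- ev_new
  }
  ev_new / (4 * m)
}

# KKT optimality violation of the L1 objective at (w, v)
kkt_violation <- function(w, v, X, y, lambda) {
  g <- logistic_gradient(w, v, X, y)
  viol_w <- ifelse(w != 0, abs(g$gw + lambda * sign(w)),
                   pmax(abs(g$gw) - lambda, 0))
  max(c(viol_w, abs(g$gv)))
}

new_catsite_model <- function(w, v, lambda, layout, threshold = 0.5,
                              fit_info = NULL) {
  structure(list(w = w, v = v, lambda = lambda, layout = layout,
                 threshold = threshold, fit_info = fit_info),
            class = "catsite_model")
}

#' Fit L1-regularised logistic regression
#'
#' Minimises the average logistic loss plus `lambda * ||w||_1` (intercept
#' unpenalised) by accelerated proximal gradient descent (FISTA) with
#' adaptive restart, run to a KKT stationarity tolerance.  The problem is
#' convex, so the returned model is the global optimum to within `tol`;
#' the solver is deterministic.
#'
#' @param data A `catsite_dataset` from [build_dataset()], or an N x d
#'   numeric matrix (then `y` must be given).
#' @param lambda L1 penalty strength (> 0).
#' @param y Labels in \{+1, -1\}; ignored when `data` is a dataset.
#' @param tol Maximal KKT violation accepted at the solution.
#' @param max_iter Iteration cap.
#' @return A `catsite_model` with fields `w` (named weights), `v`
#'   (intercept), `lambda`, `layout`, `threshold` (default 0.5 until set
#'   from an evaluation sweep) and `fit_info`.
#' @export
fit_l1logreg <- function(data, lambda, y = NULL, tol = 1e-8,
                         max_iter = 100000L) {
  if (inherits(data, "catsite_dataset")) {
    X <- data$X
    y <- data$y
    layout <- data$layout
  } else {
    X <- as.matrix(data)
    layout <- NULL
  }
  if (lambda <= 0) stop_validation("lambda must be positive")
  check_labels(y, both_classes = TRUE)
  if (any(!is.finite(X))) stop_validation("non-finite feature values")
  m <- nrow(X)
  d <- ncol(X)
  step <- 1 / lipschitz_bound(X)
  w <- numeric(d)
  v <- log(sum(y == 1) / sum(y == -1))
  zw <- w; zv <- v
  t_acc <- 1
  obj_prev <- logistic_objective(w, v, X, y, lambda)
  iters <- 0L
  kkt <- Inf
  for (it in seq_len(max_iter)) {
    iters <- it
    g <- logistic_gradient(zw, zv, X, y)
    w_new <- soft_threshold(zw - step * g$gw, step * lambda)
    v_new <- zv - step * g$gv
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    # adaptive restart on non-descent of the momentum sequence
    if (sum((zw - w_new) * (w_new - w)) + (zv - v_new) * (v_new - v) > 0) {
      zw <- w_new; zv <- v_new
      t_new <- 1
    } else {
      zw <- w_new + ((t_acc - 1) / t_new) * (w_new - w)
      zv <- v_new + ((t_acc - 1) / t_new) * (v_new - v)
    }
    w <- w_new; v <- v_new; t_acc <- t_new
    if (it %% 25L == 0L || it == max_iter) {
      kkt <- kkt_violation(w, v, X, y, lambda)
      if (kkt <= tol) break
    }
  }
  obj <- logistic_objective(w, v, X, y, lambda)
  wn <- if (!is.null(layout)) stats::setNames(w, layout$slots) else
    stats::setNames(w, colnames(X) %||% paste0("x", seq_len(d)))
  new_catsite_model(w = wn, v = v, lambda = lambda,
                    layout = layout %||% window_layout(0L),
                    fit_info = list(iterations = iters, objective = obj,
                                    kkt = kkt, converged = kkt <= tol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted catalytic probabilities
#'
#' Applies the logistic model `1 / (1 + exp(-(w'x + v)))` to each row.
#'
#' @param model A `catsite_model`.
#' @param X Feature matrix or `catsite_dataset` built with the same layout
#'   as the model.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_scores <- function(model, X) {
  if (inherits(X, "catsite_dataset")) {
    if (!identical(X$layout$slots, model$layout$slots)) {
      stop_validation(sprintf(
        "dataset layout (window %d, %d features) does not match model layout (window %d, %d features)",
        X$layout$window, X$layout$dim, model$layout$window, model$layout$dim))
    }
    X <- X$X
  }
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stop_validation(sprintf("feature matrix has %d columns but model expects %d",
                            ncol(X), length(model$w)))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), names(model$w))) {
    stop_validation("feature column names do not match the model's layout slots")
  }
  stats::plogis(drop(X %*% unname(model$w)) + model$v)
}

#' @export
predict.catsite_model <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.catsite_model <- function(x, ...) {
  cat(sprintf("<catsite_model> window %d, lambda %g, %d/%d nonzero weights, intercept %.4f, threshold %.4g\n",
              x$layout$window, x$lambda, sum(x$w != 0), length(x$w), x$v,
              x$threshold))
  invisible(x)
}

#' Tidy a fitted model into its nonzero weights
#'
#' @param x A `catsite_model`.
#' @param all Return all slots rather than only nonzero ones.
#' @param ... Unused.
#' @return A tibble with columns `slot`, `channel` and `weight`, sorted by
#'   decreasing `abs(weight)` (the "top weighted bits" view).
#' @export
tidy.catsite_model <- function(x, all = FALSE, ...) {
  out <- tibble::tibble(
    slot = names(x$w),
    channel = sub("[+-].*$", "", sub("-.*$", "", names(x$w))),
    weight = unname(x$w)
  )
  if (!all) out <- dplyr::filter(out, .data$weight != 0)
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)))
}

#' Model-level summary
#'
#' @param x A `catsite_model`.
#' @param ... Unused.
#' @return One-row tibble with `window`, `lambda`, `n_features`,
#'   `n_nonzero`, `intercept`, `threshold`.
#' @export
glance.catsite_model <- function(x, ...) {
  tibble::tibble(window = x$layout$window, lambda = x$lambda,
                 n_features = length(x$w), n_nonzero = sum(x$w != 0),
                 intercept = x$v, threshold = x$threshold)
}
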