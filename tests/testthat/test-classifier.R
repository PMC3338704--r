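random_instance <- function(n = 10, d = 5) {
  X <- matrix(rnorm(n * d), n, d)
  y <- sample(c(-1, 1), n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
  list(X = X, y = y)
}

test_that("the objective is log(2) at the origin and saturates correctly", {
  withr::local_seed(61)
  inst <- random_instance()
  expect_equal(logistic_objective(numeric(5), 0, inst$X, inst$y, 0.3),
               log(2), tolerance = 1e-12)
  # single example with an enormous positive margin: loss term vanishes
  X1 <- matrix(1, 1, 1)
  expect_equal(logistic_objective(1e4, 0, X1, 1, 0), 0, tolerance = 1e-12)
  expect_true(is.finite(logistic_objective(-1e4, 0, X1, 1, 0)))
  expect_error(logistic_objective(numeric(5), 0, inst$X, rep(2, 10), 0.1),
               class = "catsite_validation_error")
})

test_that("the objective matches naive summation on random instances", {
  withr::local_seed(67)
  for (i in 1:100) {
    inst <- random_instance()
    w <- rnorm(5); v <- rnorm(1); lam <- runif(1, 0.001, 0.1)
    expect_equal(logistic_objective(w, v, inst$X, inst$y, lam),
                 objective_brute(w, v, inst$X, inst$y, lam),
                 tolerance = 1e-12)
  }
})

test_that("the objective is convex along random segments", {
  withr::local_seed(71)
  inst <- random_instance(30, 8)
  for (i in 1:50) {
    w1 <- rnorm(8); v1 <- rnorm(1)
    w2 <- rnorm(8); v2 <- rnorm(1)
    t <- runif(1)
    lam <- 0.05
    mid <- logistic_objective(t * w1 + (1 - t) * w2, t * v1 + (1 - t) * v2,
                              inst$X, inst$y, lam)
    ends <- t * logistic_objective(w1, v1, inst$X, inst$y, lam) +
      (1 - t) * logistic_objective(w2, v2, inst$X, inst$y, lam)
    expect_lte(mid, ends + 1e-9)
  }
})

test_that("lambda_max ignores dead features, survives duplicates, and sparsifies fits", {
  withr::local_seed(73)
  X <- cbind(matrix(rnorm(40 * 3), 40, 3), 0)
  y <- rep(c(1, -1), 20)
  lm1 <- lambda_max(X, y)
  g_at_zero <- abs(crossprod(X, -y * stats::plogis(0)) / 40)
  expect_equal(unname(g_at_zero[4]), 0)
  expect_equal(lambda_max(cbind(X, X[, 2]), y), lm1, tolerance = 1e-12)
  expect_error(lambda_max(X, rep(1, 40)), class = "catsite_validation_error")

  for (i in 1:5) {
    inst <- random_instance(40, 8)
    lm <- lambda_max(inst$X, inst$y)
    fit <- fit_l1logreg(inst$X, lambda = lm * 1.01, y = inst$y)
    expect_equal(unname(fit$w), rep(0, 8))
    expect_equal(fit$v, log(sum(inst$y == 1) / sum(inst$y == -1)),
                 tolerance = 1e-6)
  }
})

test_that("small-penalty fits separate a linearly separable toy set", {
  X <- rbind(c(2, 2), c(3, 1), c(2.5, 2.5), c(-2, -2), c(-1, -3), c(-2.5, -1))
  y <- c(1, 1, 1, -1, -1, -1)
  fit <- fit_l1logreg(X, lambda = 1e-4, y = y)
  margins <- drop(X %*% unname(fit$w)) + fit$v
  expect_true(all(sign(margins) == y))
})

test_that("the solver reaches the optimum: random perturbations never improve it", {
  withr::local_seed(79)
  inst <- random_instance(50, 10)
  lam <- 0.02
  fit <- fit_l1logreg(inst$X, lambda = lam, y = inst$y)
  obj <- logistic_objective(unname(fit$w), fit$v, inst$X, inst$y, lam)
  for (i in 1:1000) {
    eps <- rnorm(11, sd = 0.01)
    pert <- logistic_objective(unname(fit$w) + eps[1:10], fit$v + eps[11],
                               inst$X, inst$y, lam)
    expect_gte(pert, obj - 1e-9)
  }
})

test_that("the fitted objective matches glmnet's coordinate-descent solution", {
  skip_if_not_installed("glmnet")
  withr::local_seed(83)
  for (i in 1:10) {
    inst <- random_instance(50, 20)
    lam <- runif(1, 0.005, 0.05)
    fit <- fit_l1logreg(inst$X, lambda = lam, y = inst$y)
    g <- glmnet::glmnet(inst$X, factor(inst$y), family = "binomial",
                        alpha = 1, lambda = lam, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
    obj_mine <- logistic_objective(unname(fit$w), fit$v, inst$X, inst$y, lam)
    obj_glmnet <- logistic_objective(as.numeric(g$beta), as.numeric(g$a0),
                                     inst$X, inst$y, lam)
    expect_equal(obj_mine, obj_glmnet, tolerance = 1e-4)
    expect_lte(obj_mine, obj_glmnet + 1e-6)
  }
})

test_that("the number of nonzero weights is non-increasing in lambda", {
  chains <- tiny_chains(n = 10, seed = 87)
  features <- chain_features(chains)
  sel <- training_selection(chains, seed = 2)
  ds <- build_dataset(features, sel, window_layout(3))
  nnz <- sapply(seq(0.001, 0.02, by = 0.001), function(lam) {
    sum(fit_l1logreg(ds, lam)$w != 0)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("fitting is deterministic: identical inputs give identical models", {
  chains <- tiny_chains(n = 6, seed = 89)
  ds <- build_dataset(chain_features(chains), training_selection(chains, seed = 3),
                      window_layout(2))
  f1 <- fit_l1logreg(ds, 0.01)
  f2 <- fit_l1logreg(ds, 0.01)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$v, f2$v)
})

test_that("predicted probabilities are a sigmoid of the linear score", {
  withr::local_seed(97)
  inst <- random_instance(20, 6)
  fit <- fit_l1logreg(inst$X, lambda = 0.01, y = inst$y)
  probs <- predict_scores(fit, inst$X)
  hand <- 1 / (1 + exp(-(drop(inst$X %*% unname(fit$w)) + fit$v)))
  expect_equal(probs, hand, tolerance = 1e-12)
  expect_true(all(probs > 0 & probs < 1))

  neutral <- fit
  neutral$w[] <- 0
  neutral$v <- 0
  expect_equal(predict_scores(neutral, inst$X), rep(0.5, 20))

  # monotone in a positively weighted feature
  j <- which(unname(fit$w) > 0)[1]
  if (!is.na(j)) {
    X2 <- inst$X
    X2[, j] <- X2[, j] + 1
    expect_true(all(predict_scores(fit, X2) >= probs))
  }
  expect_error(predict_scores(fit, inst$X[, 1:3]),
               class = "catsite_validation_error")
})

test_that("tidy and glance summarise a fitted model", {
  chains <- tiny_chains(n = 6, seed = 101)
  model <- train_model(chains, window = 2, lambda = 0.01, seed = 1)
  td <- tidy(model)
  expect_true(all(td$weight != 0))
  expect_true(all(diff(abs(td$weight)) <= 1e-15))
  expect_true(all(td$channel %in% c("RT", "OP", "ACH", "SS", "ASA", "JSD",
                                    "VJSD", "Consurf")))
  gl <- glance(model)
  expect_equal(gl$n_features, window_layout(2)$dim)
  expect_equal(gl$n_nonzero, nrow(td))
})
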