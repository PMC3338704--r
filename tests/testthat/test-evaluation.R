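test_that("negative subsampling honours the 6:1 ratio and exhaustion", {
  neg <- subsample_negatives(50L, c(10L, 20L), ratio = 6L, seed = 1)
  expect_length(neg, 12L)
  expect_true(all(!neg %in% c(10L, 20L)))
  expect_true(all(neg >= 1 & neg <= 50))

  few <- subsample_negatives(5L, 3L, ratio = 6L, seed = 1)
  expect_setequal(few, c(1L, 2L, 4L, 5L))

  expect_length(subsample_negatives(50L, integer(), ratio = 6L, seed = 1), 0L)
  expect_error(subsample_negatives(50L, 1L, ratio = 0L, seed = 1),
               class = "catsite_validation_error")
})

test_that("negative subsampling is seed-deterministic and seed-sensitive", {
  a <- subsample_negatives(200L, c(5L, 50L, 150L), seed = 7)
  b <- subsample_negatives(200L, c(5L, 50L, 150L), seed = 7)
  c <- subsample_negatives(200L, c(5L, 50L, 150L), seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("fold assignment partitions chains with balanced sizes", {
  ids20 <- sprintf("c%02d", 1:20)
  f20 <- make_folds(ids20, k = 10, seed = 1)
  expect_true(all(table(f20$fold) == 2L))
  expect_setequal(f20$chain_id, ids20)

  ids23 <- sprintf("c%02d", 1:23)
  f23 <- make_folds(ids23, k = 10, seed = 1)
  expect_true(all(table(f23$fold) %in% c(2L, 3L)))
  expect_false(anyDuplicated(f23$chain_id) > 0)

  expect_error(make_folds(ids20[1:5], k = 10), class = "catsite_validation_error")
})

test_that("the rank sweep reproduces the worked four-site example", {
  sweep <- rank_sweep(c(0.9, 0.8, 0.7, 0.6), c(1, -1, 1, -1))
  expect_equal(sweep$recall, c(0.5, 0.5, 1.0, 1.0))
  expect_equal(sweep$precision, c(1.0, 0.5, 2 / 3, 0.5))
  expect_equal(sweep$fpr, c(0, 0.5, 0.5, 1.0))
  # maximal F-measure at prefix 3
  op <- best_operating_point(sweep)
  expect_equal(op$rank, 3L)
  expect_equal(op$f, 2 * (2 / 3) * 1 / (2 / 3 + 1), tolerance = 1e-12)
  expect_equal(op$f, 0.8, tolerance = 1e-12)
})

test_that("perfect and inverted rankings trace the expected curves", {
  sweep <- rank_sweep(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(aupr(sweep), 1)
  expect_equal(auc(sweep), 1)
  # precision is 1 at full recall before any negative enters
  expect_equal(sweep$precision[sweep$recall == 1][1], 1)

  anti <- rank_sweep(c(0.9, 0.8, 0.2, 0.1), c(-1, -1, 1, 1))
  expect_equal(auc(anti), 0)
  expect_true(all(anti$fpr[1:2] > 0) && all(anti$tp[1:2] == 0))
})

test_that("sweep counts are internally consistent at every prefix", {
  withr::local_seed(103)
  scores <- runif(60)
  labels <- sample(c(1, -1), 60, replace = TRUE, prob = c(0.2, 0.8))
  sweep <- rank_sweep(scores, labels)
  expect_equal(sweep$tp + sweep$fp + sweep$tn + sweep$fn, rep(60, 60))
  expect_equal(sweep$precision, sweep$tp / (sweep$tp + sweep$fp))
  expect_equal(sweep$recall, sweep$tp / (sweep$tp + sweep$fn))
  expect_equal(sweep$fpr, sweep$fp / (sweep$fp + sweep$tn))
  expect_true(all(diff(sweep$recall) >= 0))
  expect_true(all(diff(sweep$fpr) >= 0))
})

test_that("auc equals the pair-ordering statistic, including under ties", {
  withr::local_seed(107)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # coarse: ties
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sweep <- rank_sweep(scores, labels)
    expect_equal(auc(sweep), auc_brute(scores, labels), tolerance = 1e-12)
  }
})

test_that("auc concentrates at 1/2 under label-score independence", {
  withr::local_seed(109)
  vals <- replicate(1000, {
    scores <- runif(30)
    labels <- c(rep(1, 10), rep(-1, 20))
    auc(rank_sweep(scores, labels))
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("best_operating_point prefers the balanced point and breaks ties early", {
  # P = R = 0.5 (F = 0.5) beats P = 0.9, R = 0.1 (F = 0.18)
  f_a <- 2 * 0.5 * 0.5 / (0.5 + 0.5)
  f_b <- 2 * 0.9 * 0.1 / (0.9 + 0.1)
  expect_gt(f_a, f_b)
  # where P = R the F-measure equals their common value
  sweep <- rank_sweep(c(0.9, 0.8, 0.7, 0.6), c(1, -1, -1, 1))
  pr_eq <- sweep[abs(sweep$precision - sweep$recall) < 1e-12, ]
  expect_equal(pr_eq$f, pr_eq$precision, tolerance = 1e-12)
  tie <- tibble::tibble(rank = 1:2, score = c(0.9, 0.8), label = c(1, 1),
                        tp = 1:2, fp = c(0, 0), tn = c(2, 2), fn = c(1, 0),
                        precision = c(1, 1), recall = c(0.5, 1),
                        fpr = c(0, 0), f = c(0.8, 0.8))
  expect_equal(best_operating_point(tie)$rank, 1L)
})

test_that("pooled cross-validation recovers planted signal and respects grouping", {
  chains <- tiny_chains(n = 20, seed = 113)
  cv <- cross_validate(chains, window = 2, lambda = 0.01, k = 5, seed = 3)
  expect_gte(cv$report$auc, 0.85)
  # every chain is scored in exactly one fold
  by_chain <- tapply(cv$scores$fold, cv$scores$chain_id, function(x) length(unique(x)))
  expect_true(all(by_chain == 1L))
  # counts at operating point cover the pooled set
  op <- cv$report$operating_point
  expect_equal(op$tp + op$fp + op$tn + op$fn, nrow(cv$scores))
})

test_that("cross-validation on permuted labels is at chance", {
  chains <- tiny_chains(n = 20, seed = 127)
  sel <- permute_labels_within_chains(training_selection(chains, seed = 4), 5)
  cv <- cross_validate(chains, window = 2, lambda = 0.01, k = 5, seed = 3,
                       selection = sel)
  expect_gt(cv$report$auc, 0.40)
  expect_lt(cv$report$auc, 0.60)
})

test_that("a fold whose training data has a single class is reported", {
  chains <- tiny_chains(n = 4, seed = 131)
  sel <- training_selection(chains, seed = 2)
  sel$label[sel$chain_id != chains$chain_id[1]] <- -1
  expect_error(cross_validate(chains, window = 1, lambda = 0.01, k = 2,
                              seed = 1, selection = sel),
               "single class", class = "catsite_validation_error")
})

test_that("the full-residue evaluation universe scores every residue of every chain", {
  chains <- tiny_chains(n = 6, seed = 137)
  cv <- cross_validate(chains, window = 1, lambda = 0.01, k = 3, seed = 2,
                       universe = "full")
  expect_equal(nrow(cv$scores), sum(nchar(chains$sequence)))
})

test_that("grid search covers the grid, is deterministic, and reduces to CV", {
  chains <- tiny_chains(n = 8, seed = 139)
  g <- grid_search(chains, windows = 0:1, lambdas = c(0.005, 0.01), k = 4,
                   seed = 6)
  expect_equal(nrow(g$table), 4L)
  expect_true(all(g$best$aupr >= g$table$aupr))
  g2 <- grid_search(chains, windows = 0:1, lambdas = c(0.005, 0.01), k = 4,
                    seed = 6)
  expect_identical(g$table, g2$table)

  single <- grid_search(chains, windows = 1, lambdas = 0.01, k = 4, seed = 6)
  cv <- cross_validate(chains, window = 1, lambda = 0.01, k = 4, seed = 6)
  expect_equal(single$table$aupr, cv$report$aupr)
  expect_equal(single$table$auc, cv$report$auc)
  expect_error(grid_search(chains, windows = integer(), lambdas = 0.01),
               class = "catsite_validation_error")
})

test_that("grid search selects a window wide enough to see flank-only signal", {
  # plant signal only in the conservation track, then shift that track two
  # positions towards the C-terminus: only windows >= 2 can reach it
  chains <- tiny_chains(n = 14, seed = 149, signal = 1, channels = "Consurf")
  chains$consurf <- lapply(chains$consurf, function(x) {
    c(x[-(1:2)], x[1:2])   # value for site p now sits at p + 2 (circular)
  })
  g <- grid_search(chains, windows = 0:3, lambdas = 0.005, k = 4, seed = 8)
  expect_gte(g$best$window, 2L)
})

test_that("channel ablation changes the dimension by exactly the channel's slots", {
  w <- 3L
  full <- window_layout(w)$dim
  slots <- c(RT = 20, OP = 10, ACH = 10, SS = 3 * (2 * w + 1),
             ASA = 2 * w + 1, JSD = 2 * w + 1, VJSD = 2 * w + 1,
             Consurf = 2 * w + 1)
  for (ch in names(slots)) {
    reduced <- window_layout(w, setdiff(c("RT", "OP", "ACH", "SS", "ASA",
                                          "JSD", "VJSD", "Consurf"), ch))$dim
    expect_equal(full - reduced, unname(slots[ch]), label = ch)
  }
  expect_error(ablate_channel(tiny_chains(4, 1), "Shape", 2, 0.01),
               class = "catsite_validation_error")
})

test_that("removing an identically zero channel leaves the pooled AUC unchanged", {
  chains <- tiny_chains(n = 8, seed = 151)
  chains$asa <- lapply(chains$asa, function(x) rep(0L, length(x)))
  cv_full <- cross_validate(chains, window = 1, lambda = 0.01, k = 4, seed = 3)
  cv_no_asa <- ablate_channel(chains, "ASA", window = 1, lambda = 0.01,
                              k = 4, seed = 3)
  expect_equal(cv_full$report$auc, cv_no_asa$report$auc, tolerance = 1e-9)
})

test_that("removing the only signal-bearing channel drops performance to chance", {
  chains <- tiny_chains(n = 20, seed = 157, signal = 1, channels = "Consurf")
  cv_full <- cross_validate(chains, window = 1, lambda = 0.005, k = 5, seed = 3)
  cv_abl <- ablate_channel(chains, "Consurf", window = 1, lambda = 0.005,
                           k = 5, seed = 3)
  expect_gte(cv_full$report$auc, 0.85)
  expect_gt(cv_abl$report$auc, 0.40)
  expect_lt(cv_abl$report$auc, 0.60)
})
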