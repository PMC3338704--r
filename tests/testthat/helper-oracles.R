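# Independent brute-force oracles, coded separately from the package
# implementations they check.

# KL divergence in bits, naive elementwise loop
kl_bits <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total + unname(p[i] * log(p[i] / q[i], base = 2))
  }
  total
}

jsd_brute <- function(p, q, lam = 0.5) {
  r <- lam * p + (1 - lam) * q
  lam * kl_bits(p, r) + (1 - lam) * kl_bits(q, r)
}

rvd_brute <- function(p) {
  classes <- aa_classes()
  q <- aa_background()
  aa <- aa_alphabet()
  total <- 0
  for (cls in classes) {
    P_c <- sum(p[match(cls, aa)])
    Q_c <- sum(q[match(cls, aa)])
    if (P_c > 0) total <- total + unname(P_c * log(P_c / Q_c, base = 2))
  }
  total
}

# permute labels independently within every chain: under chain-level folds
# this breaks any label-feature association while keeping train and test
# labels independent (a global permutation induces the classic negative
# dependence between disjoint subsets)
permute_labels_within_chains <- function(selection, seed) {
  withr::with_seed(seed, {
    selection$label <- stats::ave(selection$label, selection$chain_id,
                                  FUN = sample)
    selection
  })
}

ach_brute <- function(sequence) {
  h <- aa_hydrophobicity()
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  out <- matrix(0, L, 10)
  for (i in seq_len(L)) {
    for (k in 0:9) {
      win <- 2 * k + 3
      half <- (win - 1) / 2
      total <- 0
      for (j in (i - half):(i + half)) {
        if (j >= 1 && j <= L && res[j] %in% names(h)) total <- total + h[[res[j]]]
      }
      out[i, k + 1] <- total / win
    }
  }
  out
}

objective_brute <- function(w, v, X, y, lambda) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    total <- total + log(1 + exp(-y[i] * (sum(X[i, ] * w) + v)))
  }
  total / nrow(X) + lambda * sum(abs(w))
}

# AUC as the fraction of (positive, negative) pairs correctly ordered,
# ties counting one half
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

random_distribution <- function() {
  x <- stats::rexp(20)
  x / sum(x)
}

# small in-memory chain set for fast tests
tiny_chains <- function(n = 8, seed = 42, signal = 0.8, len = c(35L, 60L),
                        n_cat = 2L, channels = c("RT", "OP", "WOP", "SS",
                                                 "ASA", "Consurf")) {
  generate_chains(synth_spec(n_chains = n, length_range = len,
                             catalytic_per_chain = n_cat, signal = signal,
                             seed = seed, signal_channels = channels))
}
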