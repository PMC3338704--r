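---
title: "Catalytic-residue prediction: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic-residue prediction: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(catsite)
```

## The model

`catsite` frames catalytic-residue prediction as binary classification of
sliding-window feature vectors. Each residue contributes eight channels.
Three are *central-only* — they describe the residue itself and are
independent of the window size:

* **RT**, a 20-bit one-hot encoding in the fixed alphabet order
  `r paste(aa_alphabet(), collapse = ", ")`;
* **OP**, ten membership bits over Taylor's overlapping property classes;
* **ACH**, the mean Sweet–Eisenberg hydrophobicity over centred windows of
  3, 5, …, 21 residues (dimensionless index values; positions beyond the
  termini contribute 0 to the sum while the divisor stays the full window
  size, so terminal values shrink towards 0 rather than being dropped).

Five are *windowed* — taken at every offset $\delta = -w, \dots, +w$:
the PSIPRED (H, E, C) probabilities, binary solvent exposure, the
Jensen–Shannon conservation score, the combined VJSD score, and the
Consurf track. Offsets falling outside the chain contribute all-zero
blocks. The vector dimension is therefore $d = 40 + 7(2w+1)$, e.g. 131 at
the default $w = 6$.

The classifier is logistic regression with an L1 penalty on the weights
(never on the intercept),

$$\min_{w, v}\; \frac{1}{m}\sum_{i=1}^m \log\!\big(1 + e^{-y_i (w^\top x_i + v)}\big) + \lambda \lVert w \rVert_1 ,$$

a convex problem whose sparse solutions double as a feature-importance
report: `tidy()` on a fitted model lists the surviving slots by weight
magnitude.

### Conservation scores

Profile columns (the weighted-observed-percentage block of a PSI-BLAST
ASCII profile, kept on its native 0–100 scale by the reader) are
normalised to distributions $p$; an all-zero column carries no evidence
and falls back to the background $q$, scoring 0. Two scores are computed
against the Robinson–Robinson background frequencies shipped with
BLOSUM62 (embedded as a constant, renormalised to sum to 1):

* $\mathrm{JSD}(p, q) = \tfrac12 \mathrm{KL}(p \Vert r) + \tfrac12 \mathrm{KL}(q \Vert r)$
  with $r = (p+q)/2$ and base-2 logarithms, bounded in $[0, 1]$ and zero
  iff $p = q$;
* $\mathrm{RVD}(p) = \sum_{c} P_c \log_2 (P_c / Q_c)$ over the ten property
  classes, $P_c$ and $Q_c$ being class masses under $p$ and $q$.

Because the classes overlap, RVD is a sum of per-class relative-entropy
terms, *not* a KL divergence over a partition: it is 0 at the background
and unbounded above, but can dip slightly below 0 for columns flatter than
the background. We keep the raw value — clamping would break the exact
agreement with the definition — and rely on the per-chain min–max
normalisation that feeds VJSD to absorb the sign. VJSD itself is the
arithmetic mean of the normalised JSD and RVD tracks: the simplest
symmetric combination consistent with "combine the two normalised
scores", and monotone in both arguments.

Normalisation is per chain, not per dataset: chains arrive with
heterogeneous alignment depths and the per-chain choice makes a chain's
scores self-contained (prediction on a single chain needs no dataset
statistics). The Consurf channel is min–max normalised per chain for the
same reason — upstream conservation servers emit scores on incompatible
scales.

### Encoding details worth stating

* The OP bits follow the ten printed class definitions exactly. The
  commonly quoted example bit-string for alanine disagrees with those
  definitions (it omits the Small class, which contains A); the class sets
  are taken as authoritative, so A encodes as Hydrophobic + Small + Tiny.
* Non-canonical letters (B, Z, X, U, O) stay in the sequence; their RT and
  OP bits are all zero and their hydrophobicity index is 0, mirroring the
  terminus zero-fill convention.
* No standardisation is applied before the classifier: every channel is
  bounded by construction ([0,1] or a short hydrophobicity range), and L1
  paths are scale-sensitive, so rescaling would silently change which
  features survive.

## Training and evaluation protocol

Class imbalance is handled upstream, not by instance weighting: per chain,
six non-catalytic residues are subsampled uniformly per catalytic residue
(fewer if the chain runs out). Cross-validation folds are assigned to
*chains*, never residues — windowed features of neighbouring residues
overlap, so residue-level folds would leak test information into training.
Chains are shuffled by seed and dealt round-robin, keeping fold sizes
within one chain of each other.

For each (window, λ) cell of the grid (λ from 0.001 to 0.02 in steps of
0.001, windows 0–10, 220 cells), each fold's model scores its held-out
chains, held-out scores are pooled, and one PR/ROC sweep is computed on
the pool — one AUPR/AUC per cell rather than per-fold averages. The best
cell maximises AUPR, ties resolving to the smaller window then smaller λ.
The negative subsample and fold assignment are drawn once per grid run and
held fixed across cells, so cells differ only in their hyper-parameters.

The sweep sorts sites by score (descending; ties broken stably by chain
and position) and grows the predicted set one site at a time. AUPR is the
step-wise average precision this sweep induces (the mean of precision at
each positive's rank); a trapezoidal variant is available via
`aupr(method = "trapezoid")`. AUC is the trapezoid over the sweep with tie
blocks collapsed, which equals the Mann–Whitney pair-ordering statistic
with ties counted one half. The reported operating point maximises
$F = 2PR/(P+R)$ (earliest prefix on ties), and its score becomes the
model's prediction threshold.

Two evaluation universes are exposed: the subsampled 6:1 set (used during
tuning, matching the training distribution) and all residues of each chain
(used at prediction time, where every residue is ranked). Tables from the
two universes are not comparable — prevalence differs by an order of
magnitude.

## The solver

`fit_l1logreg()` is an accelerated proximal-gradient (FISTA) solver with
adaptive restart: gradient steps on the smooth logistic term, soft
thresholding for the penalty, step size $1/L$ with $L$ the largest
eigenvalue of $[X, \mathbf 1]^\top [X, \mathbf 1]/(4m)$ estimated by power
iteration. Convergence is declared when the KKT violation drops below
`tol` (default $10^{-8}$), checked every 25 iterations; the solver is
deterministic, exact zeros come from the soft threshold (so sparsity is
genuine, not a cutoff), and for $\lambda \ge \lambda_{\max}$ it returns
$w = 0$ with the closed-form intercept $\log(m_+/m_-)$. The contract is
the optimum, not the algorithm: tests verify agreement with an independent
coordinate-descent solver (glmnet) to far better than $10^{-4}$ on the
objective, and that a thousand random perturbations never improve a
returned solution. Margins are handled in log-space (`log1p(exp(·))`
split by sign), stable beyond $\pm 10^4$.

## The synthetic benchmark

`synth_spec()` / `generate_chains()` produce complete datasets with a
planted signal of strength $\sigma \in [0, 1]$:

* background residues drawn from the BLOSUM62 background; catalytic
  residues redrawn from the polar/charged pool with probability $\sigma$;
* profile columns Dirichlet-distributed (concentration 50) around
  $(1-\sigma) q + \sigma\,\mathbf 1_{\text{true residue}}$ at catalytic
  sites and around $q$ elsewhere — mild noise rather than exact
  background, so min–max normalisation never sees a constant track; at
  $\sigma = 1$ catalytic columns are exactly one-hot;
* coil probability boosted towards 1 by $\sigma$ at catalytic sites
  (Dirichlet, concentration 30, base (0.35, 0.25, 0.40));
* exposure forced with probability $\tfrac12 + \sigma/2$ at catalytic
  sites against a 0.5 baseline; written to disk as real-valued
  accessibilities so the reader's binarisation path is exercised;
* conservation scores unit-normal, shifted $+2\sigma$ standard deviations
  at catalytic sites.

At $\sigma = 0$ every rule collapses to its background and labels are
independent of all features (pooled CV AUC $0.5 \pm 0.05$); recovery is
monotone in $\sigma$, and the default benchmark (50 chains of 60–120
residues, 3 catalytic sites each, $\sigma = 0.8$) is separable nearly
perfectly. That is what passing tests show — that the pipeline finds
signal where signal exists and finds none where none exists. The
generator does **not** emulate real alignment depth, phylogenetic
correlation between chains, annotation noise, or the much weaker and
partially structural signal of real catalytic sites, so synthetic AUPR/AUC
say nothing about real-data performance levels.

One protocol subtlety: the permutation null shuffles labels *within*
chains. A global permutation fixes the total number of positives, which
makes training-fold and held-out label statistics negatively dependent and
biases the null AUC below 0.5; within-chain permutation keeps held-out
chains independent of the training folds and centres the null at 0.5.

## Defaults and problem sizes

| Parameter | Default | Why |
|---|---|---|
| window $w$ | 6 | the customary tuned operating point for this protocol; wide enough for the windowed channels to capture flanking context |
| λ | 0.01 | midpoint of the tuning grid; a package choice — rerun `grid_search()` for any new dataset |
| subsampling ratio | 6 | the stated negative:positive training ratio |
| folds $k$ | 10 | the stated cross-validation protocol |
| ASA binarisation | 5.0 (relative-accessibility units) | the attribute is defined as binary but the cut is not published; configurable |
| solver `tol` | $10^{-8}$ KKT | tight enough that weight signs and AUPR are solver-independent |
| JSD mixture weight | 0.5 | the symmetric divergence with the $[0,1]$ bound |

The test suite and the acceptance script run the benchmark at 50 chains
(10-fold CV), ablations at 10 chains, and restricted 2×2 grids; these
sizes were chosen so the full protocol shape is exercised while the whole
suite stays fast on one CPU.

## Known limitations

* The upstream predictions (PSI-BLAST profile, PSIPRED, accessibility,
  Consurf) are inputs; the package parses their outputs but does not run
  them, and the choice of database/iterations behind a profile is the
  user's.
* The combined conservation score admits several published variants; the
  forms implemented here (Capra–Singh Jensen–Shannon divergence,
  mean-of-normalised combination) are documented, configurable choices.
* Model files are versioned JSON and refuse layouts or versions they were
  not built for; there is no migration between versions.
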