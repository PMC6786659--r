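---
title: "Ranking cancer driver genes with kernel one-class SVMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking cancer driver genes with kernel one-class SVMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncorank)
```

## The model

Driver-gene discovery is a positive-unlabeled problem: we have a list of
known drivers but no trustworthy list of non-drivers, because a gene absent
from the catalogues may simply not have been characterized yet.  `oncorank`
therefore trains a one-class SVM on the positives only.  Given training
drivers $g_1,\dots,g_N$ and a positive-semidefinite gene kernel $K$, the
scoring function is

$$ f(g) = \sum_{i=1}^N \alpha_i\, K(g_i, g), $$

with $\alpha$ solving

$$ \min_\alpha \tfrac12 \alpha^\top K \alpha
   \quad\text{s.t.}\quad \textstyle\sum_i \alpha_i = 1,\;
   0 \le \alpha_i \le \max(C, 1)/N. $$

Only the *ranking* induced by $f$ is used, so no offset term is needed.
The parameterization deserves a note: one-class SVMs are conventionally
$\nu$-parameterized, but the tuning protocol we follow speaks of a
regularization parameter $C$ on the grid $2^{-5/2},\dots,2^{5/2}$.  We
adopt the dual above as our convention: for $C \le 1$ the box forces the
fully uniform solution $\alpha_i = 1/N$ (scores become mean similarities to
the training set), and larger $C$ lets weight concentrate on the most
mutually similar training drivers.  This convention is validated against a
brute-force simplex-grid oracle in the test suite, not against any external
implementation.

### Gene kernels

* **Mutation kernel.**  Each gene is a 3-vector $\Phi(g)$ computed from a
  somatic mutation table.  OG mode: number of damaging missense mutations
  (PolyPhen2 strictly greater than 0.447), total missense count, and the
  Shannon entropy (natural log) of the empirical distribution of missense
  protein positions — hotspot clustering gives low entropy.  TSG mode:
  frameshift count, loss-of-function count (nonsense + frameshift), and
  splice-site count.  $K_{\text{mutation}}(g,g') = \Phi(g)^\top\Phi(g')$.
* **PPI kernel.**  $K_{\text{PPI}} = \exp_M(-L)$ with
  $L = I - D^{-1/2}AD^{-1/2}$ the normalized Laplacian of the interaction
  network.
* **Degree kernel.** $K_{ij} = d_i d_j$, a rank-one control capturing only
  connectivity volume.
* **Integrated kernel.**  The plain average
  $(K_{\text{mutation}} + K_{\text{PPI}})/2$; no multiple-kernel-learning
  weights and no trace normalization.

### Disease kernels and the multitask mode

Cancer-type-specific training replaces genes by (gene, disease) pairs with
$K_{\text{pair}} = K_{\text{gene}} \times K_{\text{disease}}$.  Four
disease kernels are provided: uniform ($\equiv 1$; pools everything),
Dirac ($[d = d']$; no sharing), the multitask compromise
$(\text{uniform} + \text{Dirac})/2$, and the descriptor kernel
$(\Psi(d)^\top\Psi(d') + \text{uniform} + \text{Dirac})/3$, where
$\Psi(d)$ is a binary 43-vector over 12 tumor-type and 31 localization
characteristics.  The printed source vocabulary actually lists 32
localization names while stating a 43-dimensional descriptor; we keep the
43-dimensional contract and drop "squamous cell", the one entry that is a
histological rather than anatomical characteristic.

### Evaluation

The consistency error is $CE = \#N \times (1 - AUC)$, the mean number of
negative genes ranked above held-out drivers.  AUC uses Mann–Whitney pair
counting with half credit for ties (the tie convention is our choice; the
protocol we follow does not state one), and the test suite verifies it
equals the trapezoidal area under the tie-grouped ROC curve.  Outer
evaluation is repeated $k$-fold cross-validation over the gold standard
(defaults: $k = 5$ pan-cancer, $k = 2$ per disease, 2 repeats); negatives
are the universe minus the task's entire gold set.  In the per-disease
setting the task's gold standard is that disease's own driver list, so
drivers known only for *other* diseases count as negatives — a training
regime that promotes unrelated diseases' drivers pays for it in CE.  Inner
tuning picks $C$ from the 11-value grid minimizing mean inner-CV CE (ties
resolve to the smallest $C$); for multitask models the inner folds are
drawn from the model's actual training set, the full pair list, not just
the query disease's few genes, whose singleton folds would make the
selection arbitrary.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `C` grid | $2^{-5/2} \dots 2^{5/2}$ | 11 half-powers of two | stated tuning protocol |
| PolyPhen2 damaging threshold | 0.447, strict | score in [0,1] | stated definition of damaging missense |
| `standardize` (mutation kernel) | `TRUE` | z-score per column | raw counts span orders of magnitude and would dominate the kernel average; documented assumption |
| `k`, `repeats` | 5 / 2 (pan-cancer), 2 / 2 (per disease) | folds × repeats | stated protocol |
| `n_bins` (degree shuffle) | 20 | bins by decreasing degree | stated randomization control |

## The synthetic world

`synth_generate()` emulates the statistical structure the method exploits,
not real genomes:

* Per-gene, per-category mutation counts are Poisson with a log-normal
  gene-level multiplier (`gene_length_dispersion = 0.5`) standing in for
  gene length and background-rate heterogeneity — the reason raw frequency
  ranking fails.
* TSG-like drivers multiply their nonsense/frameshift/splice rates, and
  OG-like drivers gain extra damaging (PolyPhen2 in (0.6, 1)) missense
  mutations concentrated on three positional hotspots.  The median
  multiplier is `driver_effect = 8`, but each driver draws its own effect
  `driver_effect^u`, `u ~ N(1, 0.5)` truncated at 0: real driver lists
  contain heavily mutated genes *and* drivers with almost no mutations, and
  this penetrance spread is what makes the mutation and network kernels
  complementary rather than redundant.  With `driver_effect = 1` every
  multiplier is exactly 1 — the null world is signal-free by construction.
* The PPI network is preferential attachment (`m = 2`) plus driver modules:
  within a module, driver pairs gain an edge with probability
  `module_boost = 0.3`, but only a `module_participation = 0.7` fraction of
  drivers joins a module at all — drivers are *more likely* to sit in
  complexes, not guaranteed to.  Non-participating drivers carry no
  network signal and can only be found through mutations, and vice versa.
* In the multi-disease world (6 diseases by default), each disease has 3
  globally shared plus 3 specific drivers; diseases come in pairs that
  share most of their specific drivers and their interaction module.
  Descriptors give every disease a common "carcinoma" type bit, a
  pair-shared localization bit, and a unique localization bit, so
  descriptor inner products (3 / 2 / 1 for self / pair / unrelated) track
  driver-set overlap — unrelated real cancer types also never have
  fully-disjoint descriptors.

What a green test does **not** establish: nothing here models mutational
signatures, trinucleotide context, copy-number alterations, sample-level
heterogeneity, hub bias from study intensity, or the $\sim$19,000-gene
scale of real catalogues (the default universe is 400 genes, so absolute
CE values are not comparable to published ones; only orderings and
calibration properties are asserted).

## Numerical choices

* The matrix exponential uses the symmetric eigendecomposition of $L$
  (exact for symmetric matrices); the test suite checks it against a
  30-term truncated series at $10^{-8}$ and the two-node closed form
  $(1 \pm e^{-2})/2$.
* The dual QP is solved by deterministic SMO-style pairwise coordinate
  descent (most-violating pair, exact line search, KKT gap below
  $10^{-8}$ relative); correctness is defined by a brute-force
  constrained-simplex grid oracle.  Fits are bit-reproducible.
* Kernels are accepted as numerically PSD when the smallest eigenvalue is
  $\ge -10^{-8}$ relative to the spectral radius.
* Ties in rankings break lexicographically by gene identifier; fold
  assignment, shuffles, and generation are all seeded, with child seeds
  derived arithmetically (no global RNG state leaks).
* Isolated or network-absent genes enter the diffusion kernel with unit
  self-similarity and zero off-diagonal (block extension, PSD-preserving);
  network proteins absent from the mutation universe are dropped before
  alignment.  Genes outside the network are thus scoreable but receive no
  network signal.

## Design choices where the design was open

* **Entropy formula**: Shannon entropy, natural log, over distinct
  positions, with no normalization by gene length or mutation count — the
  simplest reading of "entropy of the spatial distribution"; mutations
  with missing position are excluded from the distribution but still
  counted in the missense total, so counts never silently shrink.
* **Missing PolyPhen2** scores count as non-damaging.
* **Gene identifiers** are case-sensitive symbols matched exactly; no alias
  resolution.
* **Aggregation regime and shared drivers**: a gene held out for disease
  $d$ may be a known driver of other diseases.  The aggregation regime
  (a plain gene-set model) must drop such genes from its pooled training
  set to keep them scoreable; the multitask regimes legitimately keep the
  gene's *other-disease* pairs — exploiting cross-task annotations is the
  point of multitask sharing.
* **Per-fold CE averaging**: the mean of per-fold CEs is the primary
  statistic (rather than the CE of a mean ROC curve); per-fold values are
  returned so either can be computed.
* **Benchmark repeats**: the 6-disease regime comparison uses 4 repeats of
  2-fold CV; with 15 drivers per class, 2 repeats leave the regime means
  dominated by fold-assignment noise.

## Known limitations

* OC-SVM is the only training algorithm; PU-learning with bootstrapped
  negatives or iterative relabeling is out of scope.
* The kernel set is fixed (no multiple kernel learning, no random-walk or
  regularized-Laplacian graph kernels).
* Absolute CE values at synthetic scale are not comparable to published
  full-catalogue values.
* The CLI covers reproducible file-based runs but no plotting; TSV outputs
  are meant for external plotters.
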