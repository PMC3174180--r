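---
title: "Seed-site context features, AMOSA-SVM feature selection, and decision-value ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-site context features, AMOSA-SVM feature selection, and decision-value ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarsvm)
```

# The problem

MicroRNAs (~22-nt non-coding RNAs) repress target mRNAs mainly through
"seed" complementarity: pairing between miRNA positions 1–8 (counted from
the 5' end) and a site in the target's 3'UTR. Machine-learning target
predictors train a classifier on labeled miRNA–mRNA pairs, but a single
performance criterion (say accuracy) hides the trade-off between false
negatives and false positives. This package treats feature selection as a
multi-objective search: an archived multi-objective simulated annealer
(AMOSA) explores 90-bit feature masks, scored by the cross-validated
sensitivity (*Sn*), specificity (*Sp*) and Matthews correlation
coefficient (*MCC*) of an RBF-kernel SVM, and keeps an archive of
Pareto-non-dominated masks. A final mask is chosen from the archive and the
SVM's decision value ranks candidate interactions.

# Seed-site model

A **6mer core** is a 6-nt UTR window that pairs antiparallel with miRNA
seed positions 2–7 (or, alternatively, 3–8) with Watson–Crick pairs
throughout and at most one G:U wobble. Cores on the 2–7 register are
upgraded: **7mer-m8** when the UTR base opposite miRNA position 8 is
Watson–Crick paired (the upgrade demands a true complementary pair, so a
G:U at position 8 never upgrades), **7mer-A1** when the UTR base aligned
with miRNA position 1 is an adenosine (an identity test, not a pairing
test), and **8mer** when both hold. Coordinates are 1-based closed
intervals on the UTR as written; with miRNA position 1 aligned to UTR
position $p_1$, miRNA position $k$ faces UTR position $p_1 - (k-1)$
(antiparallel duplex geometry).

Two design points were genuinely open and are resolved as follows:

* **3–8 register cores.** They are detected and reported as 6mers but are
  never upgraded to 7/8mer categories, which are defined on the 2–7 core.
  When one window matches on both registers, only the 2–7 site is emitted
  (it is the one carrying upgrade semantics); overlapping *windows* each
  produce their own site, and de-duplication happens only in
  `effective_site()` (priority 8mer > 7mer-m8 > 7mer-A1 > 6mer, ties by
  fewer wobbles then leftmost position).
* **3'-supplementary pairing.** The binary flag tests Watson–Crick pairing
  of all four UTR bases opposite miRNA positions 13–16 in the ungapped
  anchored register. Additional pairing at positions 12/17 is reported as a
  count in the site context but never changes the binary value, following
  the flag definition rather than the count-flavored feature name.

The **AU-rich flank** flag pools up to 30 nt on each side of the site
(truncated at UTR ends, site excluded) and fires when the A+U fraction is
at least 60% — the boundary is inclusive.

# The 90-feature catalog

Features are indexed 1–90 in seven categories (sizes 12/4/4/16/16/6/32).
Nucleotides are ordered A, U, G, C; dinucleotides vary the second letter
fastest; seed base pairs (miRNA:target) are ordered A:U, U:A, U:G, G:C,
G:U, C:G; consecutive-pair bigrams take first-pair blocks A:U, U:A, G:C,
C:G, G:U, U:G with the second pair in the same order, excluding the four
wobble–wobble combinations (a single wobble per site makes them
impossible), which yields exactly 32 bigram features ending at index 90.
Category 1 is reconstructed as 4 site-category counts + 4
supplementary-pairing flags + 4 AU-flank flags (in site-category order
6mer, 7mer-m8, 7mer-A1, 8mer); this 4+4+4 layout is this package's
declared reconstruction — it satisfies the known size (12) and the known
name of index 6, but the original source for the category-1 sublist is not
public. "Frequency" is implemented as the raw count within its region:
regions have near-constant length, counts keep features integer and
exactly testable, and the SVM's min–max scaler absorbs scale.

Category 6/7 features count pairs over the *required* seed-match positions
only (2–7 for 6mer and 7mer-A1, 2–8 for 7mer-m8 and 8mer, 3–8 for a 3–8
register core); the A1 anchor is excluded. Hence the invariants
$\sum \text{cat6} = $ number of required positions and
$\sum \text{cat7} = $ that number minus one, which the tests exercise.

A pair with no detected site gets the all-zero vector; the packaged
published selection (39 features, of which 22 are "common", i.e. retained
by at least 90% of archived solutions in the original optimization) ships
inside `feature_catalog()` so that the published model configuration can
be instantiated without re-running the optimizer.

# Classifier

`train_model()` fits a C-classification SVM with RBF kernel
$K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2)$ through libsvm
(e1071), with fixed tolerance $10^{-3}$ and shrinking enabled, so fits are
deterministic. Features are min–max scaled to $[0,1]$ with a scaler fitted
on training data only and stored in the model (the original work does not
state its scaling; min–max is the libsvm-guide default and makes
predictions invariant to pre-scaling of columns). The decision value
$d(x) = \sum_i y_i \alpha_i K(x_i, x) + b$ is the prediction score;
class $+1$ requires $d(x) > 0$, an exact 0 is conservatively non-target.
$(C, \gamma)$ are selected on a held-out validation set by
`grid_select()`; ties prefer the smallest $C$, then the smallest
$\gamma$ (simpler models first). The published choice of $(C, \gamma)$ is
not recoverable, so they are ordinary configuration here; the package
default $C = 8$, $\gamma = 1/p$ (with $p$ the feature count) is a standard
mid-grid operating point.

Cross-validated objectives use stratified 5-fold CV with a seeded shuffle,
and pool confusion counts over folds before computing (*Sn*, *Sp*, *MCC*)
("micro" aggregation; robust when folds contain few negatives). Per-fold
("macro") averaging is available via `aggregate = "per-fold"`. The MCC
convention at a zero denominator factor is 0.

# AMOSA

Solutions are 90-bit masks; objectives are maximized. The archive keeps
mutually non-dominated solutions under a soft limit SL; whenever the size
passes SL it is reduced to the hard limit HL by single-linkage clustering
in objective space, keeping from each cluster the member with the minimal
average distance to its cluster mates (ties: lexicographically smallest
bitstring — a deterministic convention). Initialization draws `n_init`
random masks and refines each by hill climbing (a one-bit-flip neighbor is
accepted only if it dominates).

The annealing acceptance uses the *amount of domination*
$\Delta(a,b) = \prod_{i:\, a_i \ne b_i} |a_i - b_i| / R_i$, with ranges
$R_i$ tracked as the running min/max of each objective over all solutions
evaluated so far (floored at $10^{-6}$) — the underlying formulation needs
objective ranges but none are fixed for (*Sn*, *Sp*, *MCC*). The reference
description of the algorithm gives a three-outcome acceptance sketch; the
exact case probabilities are not recoverable from it, so this
implementation's contract is: (a) the new point dominates the current
point — accept, and insert into the archive when no member dominates it;
(b) the current point dominates the new point — accept with probability
$1/(1+\exp(\bar\Delta/T))$ where $\bar\Delta$ averages the domination of
the current point and of any dominating archive members over the new
point; (c) mutually non-dominating — accept and insert when no archive
member dominates it, otherwise accept with the same probabilistic form.
This preserves the three-outcome structure and the usual simulated
annealing temperature dependence (permissive at high $T$). Single-bit
perturbation re-flips when it would produce the empty mask. All randomness
derives from one schedule seed; runs are exactly reproducible.

Schedule defaults (`Tmax = 100`, `Tmin = 1e-4`, `alpha = 0.9`, 50
iterations per temperature, 10 initial solutions, 20 hill-climb steps,
HL = 30, SL = 60) are conventional simulated-annealing settings for an
expensive wrapper objective; every value is configurable. The test suite
and the acceptance script use a deliberately reduced schedule
(`Tmax = 1`, `Tmin = 0.1`, `alpha = 0.5`, 6 iterations per temperature, 3
initial solutions, 10 hill-climb steps, HL = 10, SL = 20 — roughly 60 SVM
cross-validation evaluations per run) so that replicated selection runs on
578-example datasets complete in minutes on one CPU; these problem sizes
are the package's own benchmark choices.

`select_features()` picks, among archived masks, the one with the highest
pooled cross-validation accuracy on the (balanced) training data — reusing
the objective evaluations' fold seed, since no separate selection dataset
is defined — with ties resolved by larger MCC, then fewer selected
features, then lexicographic order. The returned mask is therefore always
an archive member. `common_features()` uses the inclusive threshold
$\lceil 0.9\, n \rceil$ members.

# Ranking analyses

`rank_interactions()` ranks by decision value, descending, mean ranks for
ties. Percentile membership uses the inclusive ceiling cutoff
$\text{rank} \le \lceil p/100 \cdot n \rceil$, a deterministic convention
that behaves sensibly on short lists (e.g. a 28-item list). The percentile
is computed over the full ranked list, not only predicted positives.
Rank-list comparisons use the two-sided Wilcoxon rank-sum test (exact
enumeration below 20 observations per group when tie-free, tie-corrected
normal approximation otherwise), and `resampled_metric_comparison()`
re-draws fixed-size subsamples without replacement, recomputes *Sn*, *Sp*,
*MCC* and precision for two scorers, and tests per metric across repeats.

# What the synthetic generator emulates — and what it does not

`gen_dataset()` mirrors the structure of the training corpus the method is
designed for: 289 positive and 289 negative pairs, ~22-nt miRNAs, 300-nt
UTRs at 50% GC (A=U, G=C split). Positives always receive a planted seed
site (categories drawn 8mer 40%, 7mer-m8 30%, 7mer-A1 20%, 6mer 10% —
skewed toward strong sites, as curated positive sets are), with AU-rich
flanks in 90% and 3'-supplementary pairing in 50%; negatives receive a
weak 6mer with probability 0.2 and no enrichment, mimicking hard negatives
that are not trivially site-free. `implant_site()` guarantees by
construction that the planted site scans back at the requested category
and position (guard bases prevent accidental upgrades).
`gen_feature_matrix()` skips the sequence layer entirely and plants a
2-SD class mean shift in five designated feature columns (53, 54, 56, 57,
58 — five of the six seed base-pair features, so the planted signal is
concentrated in one catalog category), which is the test bed for the
selection wrapper.

What passing tests on these data do **not** show: real negatives are not
random background (they share expression context with positives), real
feature signal is far weaker and correlated across categories, and UTRs
carry composition structure (conservation, accessibility) that the
generator ignores. The synthetic benchmarks validate the machinery —
detection, bookkeeping, optimization, ranking — not biological accuracy,
and the published benchmark figures of the original study are not
reproducible from these synthetic conditions.

# Numerical choices and degenerate inputs

* Empty site list → all-zero feature vector (not an error); empty feature
  mask → error everywhere.
* MCC with a zero denominator factor is 0; Sn/Sp demand at least one
  example of the relevant class; precision demands at least one predicted
  positive.
* AUC is the rank-based Mann–Whitney statistic with half credit for ties;
  it equals the brute-force ordered-pair fraction (tested).
* The FSR table rounds to 2 decimals, matching the precision at which
  such tables are conventionally reported.
* Archive ties (identical objective vectors) are allowed as long as no
  member dominates another; duplicate bitstrings are never inserted twice.
* Running the recovery benchmark compares the planted category's FSR to
  the *mean* FSR of the other categories; single small noise categories (4
  features) are too variable for an every-category comparison to be a
  stable statistic.

# Known limitations

* The category-1 sublist layout is a declared reconstruction (see above).
* The acceptance-probability form and schedule constants of the annealer
  are this implementation's contract; other AMOSA implementations may
  accept with different probabilities while preserving the same
  three-outcome structure.
* Model serialization uses RDS, which is R-version-portable but not a
  cross-language exchange format.
* No thermodynamic, conservation or expression features; no genome-wide
  conserved-target scanning.
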