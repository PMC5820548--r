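---
title: "Multiview sequence features and two-step selection for cancerlectin prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview sequence features and two-step selection for cancerlectin prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cancerlectins — lectins functionally associated with cancer processes —
share strong sequence homology with ordinary lectins, so homology search
alone separates the two classes poorly. `lectinpred` instead treats the
problem as supervised binary classification on fixed-length numeric
encodings of the primary sequence, combining four feature views that
capture complementary signals, balancing the training classes with SMOTE,
pruning the feature space with a two-step filter/wrapper selection, and
scoring a Random Forest under stratified 5-fold cross-validation.

This vignette explains each stage's model and assumptions, the parameters
that matter, the numerical conventions chosen where the method leaves
room, and what the synthetic-data tests do and do not demonstrate.

## Feature views

### CTD (147 features)

Seven physicochemical properties each partition the 20 amino acids into
three groups (the table ships as `inst/extdata/ctd_groups.tsv` and is
validated as a partition on load). Per property:

* **Composition** — the fraction of residues in each group,
  $(N_1/L, N_2/L, N_3/L)$; sums to 1.
* **Transition** — the frequency of dipeptides whose residues fall in
  different groups, $(N_{\alpha\beta}+N_{\beta\alpha})/L$ for the three
  unordered group pairs. The classical formula divides by $L$ even though
  only $L-1$ dipeptides exist; we keep that convention as the default and
  expose `denominator = "L-1"` for the dipeptide-count normalization. The
  two differ by a factor $L/(L-1)$, immaterial for tree classifiers but
  worth fixing for reproducibility.
* **Distribution** — for each group, the 1-based positions of its first
  occurrence and of the occurrences at the 25/50/75/100% quantiles of its
  count, divided by $L$. The quantile index is $\lceil q N_i \rceil$
  (ceiling), the convention of the widely used CTD implementations; the
  choice only moves a feature by one residue position. A group absent
  from a (short) sequence contributes five zeros rather than an error, so
  the dimension is always exactly $7 \times (3+3+15) = 147$.

CTD is invariant to any residue substitution that preserves all seven
group memberships (F and W are one such pair), which the tests exploit.

### Classical PseAAC (70 features)

The classical pseudo amino acid composition augments the 20 occurrence
frequencies $f_u$ with $\lambda$ sequence-order correlation factors

$$\theta_j = \frac{1}{L-j}\sum_{i=1}^{L-j}
  \frac{1}{3}\left[(H^1_i - H^1_{i+j})^2 + (H^2_i - H^2_{i+j})^2 +
  (M_i - M_{i+j})^2\right],$$

all jointly normalized by $\sum f_i + w \sum \theta_j$ so the
$(20+\lambda)$ components are non-negative and sum to 1. Defaults are
$\lambda = 50$ and $w = 0.15$; $\lambda$ bounds the usable sequence
length from below at $\lambda + 1 = 51$ residues, and sequences shorter
than that are rejected with an explicit message (a smaller `lambda` can
be chosen for a whole dataset when short sequences are unavoidable).
Whether $f_u$ are counts or frequencies cancels in the normalization; we
use frequencies.

The residue indices $H^1$ (hydrophobicity), $H^2$ (hydrophilicity,
Hopp–Woods) and $M$ (side-chain mass) are the canonical classical-mode
PseAAC constants, shipped raw in `inst/extdata/pseaac_indices.tsv` and
standardized at load to mean 0 and *population* (divide-by-20) SD 1 over
the 20 residues — the standardization classical PseAAC uses. A different
constants table would shift real-data results slightly; the packaged one
is the de-facto standard.

### PSSM evolutionary features (120)

A PSI-BLAST ASCII profile (`-out_ascii_pssm`) is parsed into its first
20-column log-odds block ("substitution scores"; the weighted-percentage
block is ignored), with columns remapped from the file header's order to
the package's alphabetical residue order so feature names are stable.
Scores are sigmoid-scaled, $f(x) = 1/(1+e^{-x})$, *before* both derived
feature sets, including the column means used for centering:

* **PSSM-AAC** — the 20 column means of the scaled matrix.
* **PsePSSM** — for each column $k$ and lag $j = 1..\gamma$ the
  autocovariance $\frac{1}{L-j}\sum_i (E_{i,k}-\bar E_k)(E_{i+j,k}-\bar
  E_k)$, flattened residue-major, lag-minor. Default $\gamma = 5$ gives
  100 features and requires $L > 5$.

Running PSI-BLAST itself is out of scope; profiles are consumed as
files. A record without a profile is skipped by default (`"skip"`); the
`"pseudo"` fallback substitutes the BLOSUM62 row of each observed
residue through the same sigmoid — a position-independent approximation
useful for demonstrations, never a replacement for a real profile, and
logged per record.

### Disorder summaries (28)

Per-residue disorder scores in $[0,1]$ (any predictor; VSL2 is the
typical source) are summarized as: mean and SD of all scores; counts of
disordered/ordered segments (maximal runs at or above / below the
threshold); min/max lengths of each segment kind (0 when a kind is
absent, keeping the dimension fixed for fully ordered or fully
disordered proteins); and the mean score of each amino acid (0 for
absent residues). The segmentation threshold defaults to 0.5, the
published decision boundary of VSL2; the SD is the population form. Both
conventions are configurable because the method description leaves them
open.

## SMOTE balancing

Training sets for this problem are typically imbalanced (e.g. 178
positives vs 226 negatives, where balancing appends exactly 48 synthetic
rows). `smote_balance()` equalizes classes by synthesizing minority
points $x + u\,(x_{nn} - x)$, $u \sim U[0,1]$, with $x_{nn}$ one of the
$k = 5$ nearest minority neighbours under Euclidean distance on the raw
features (an option z-scores features for the distance computation only).
Base samples are cycled in a seeded random order, so the procedure is
exactly reproducible and matches the original SMOTE scheduling when the
oversampling rate is not a multiple of 100%. Every synthetic point lies
in the minority class's componentwise bounding box; originals pass
through bit-identical and synthetic rows are flagged in a `synthetic`
column.

## Two-step feature selection

**Step 1 — ReliefF filter.** Each feature is scored by how much nearer
(in that feature) an instance's $k$ nearest same-class neighbours are
than its $k$ nearest opposite-class neighbours, with differences
normalized by the feature's range and features min-max scaled for the
neighbour search. We use the ReliefF variant — $k = 10$ hits/misses,
all instances sampled — rather than original Relief's single random
neighbour, because it is the de-facto standard and markedly less noisy;
both $k$ and the sample size are configurable. Constant features score
exactly 0. The retained set is every feature with score **strictly
greater than 0**.

**Step 2 — SFS wrapper.** Starting from the empty set, the candidate
(taken from the retained features in rank order) whose addition
maximizes 5-fold cross-validated Random-Forest accuracy is added, up to
`cap` features. The fold split is drawn once and reused across all steps
and candidates so accuracies are comparable; accuracy ties resolve in
candidate order (higher ReliefF rank first, then lower index). The
selected subset is the shortest prefix attaining the maximum accuracy in
the trace. The full $O(p^2)$ sweep over hundreds of candidates is
expensive; `cap` (and the `trees` count of the wrapped forest) are the
practical dials, and the trace plus `autoplot()` selection curve make
the accuracy/size trade-off visible.

## Evaluation

Stratified 5-fold cross-validation (class proportions preserved per
fold; the method description says only "randomly split", stratification
removes one source of variance). Confusion counts are pooled over folds;
Sn, Sp, Acc and MCC follow the standard confusion-matrix formulas with
MCC defined as 0 whenever a denominator factor vanishes. The ROC sweeps
all distinct out-of-fold scores (for RF, the fraction of trees voting
positive); AUC is computed by both the trapezoid rule and the
Mann–Whitney rank statistic, which agree to numerical precision and are
cross-checked against each other (and pROC) in the tests.

SMOTE placement is explicit: `"pre_split"` balances the whole matrix
before splitting — the published procedure, which lets synthetic points
fall into test folds and therefore flatters the estimate; `"per_fold"`
balances only each training part, the leakage-safe alternative; `"off"`
disables it. The default in `run_pipeline()` is `pre_split` for fidelity
to the published workflow, with `per_fold` documented here as the
methodologically safer choice.

The Random Forest uses 100 trees, $\sqrt{M}$ features per split and
unlimited depth — the original method reports only "default parameters"
of its toolkit, so we pin modern defaults and log them in the run
manifest. `compare_classifiers()` evaluates alternatives (1-NN, naive
Bayes, logistic regression, decision tree, majority dummy) under
identical folds for the classifier-comparison experiment.

## Synthetic data: what it shows and what it cannot

`simulate_dataset()` generates the study conditions for all tests:
sequences drawn i.i.d. from class residue-frequency profiles (the
positive class carries `separation` extra mass on hydrophobic residues;
0.2 by default), PSSM files in the full PSI-BLAST ASCII layout whose raw
scores favour the observed residue by +4 over integer noise (SD 2), and
disorder tracks built as window-5 moving averages of uniform noise
around class means 0.6/0.4, clipped to $[0,1]$. Minimum length 56
guarantees every encoder's precondition ($\lambda+1 = 51$,
$\gamma+1 = 6$). Generation is byte-deterministic given the seed, and
`make_imbalanced()` reproduces imbalanced designs such as 178/226.

These fixtures validate *mechanics*: format round-trips, dimensional
contracts (147 + 70 + 120 + 28 = 365), invariances, the direction of the
SMOTE effect, and that selection recovers planted signal. They are
i.i.d. compositional caricatures — no domain structure, no real
evolutionary conservation, no homology between records — so passing
tests say nothing about absolute accuracy on real lectin data, which
additionally requires genuine PSI-BLAST profiles and disorder
predictions.

Problem sizes were chosen to make the suite and the acceptance script
complete in minutes while keeping every check statistically meaningful:
e.g. the SFS-recovery simulation uses n = 200 with 3 informative + 17
noise features over 10 seeds and a 40-tree evaluator; the full-pipeline
accuracy check uses 66 records at separation 0.35; the SMOTE ablation
uses 160 records at minority fraction 0.25 with only the compositional
views, where the classifier is imperfect enough for imbalance to bite.

## Known limitations

* Real-data performance depends on inputs this package deliberately does
  not produce (PSI-BLAST profiles, disorder predictions) and on the exact
  PseAAC constants table; published benchmark numbers are therefore not
  reproducible from the package alone.
* `pre_split` SMOTE leaks synthetic information into test folds by
  construction; use `per_fold` when an unbiased estimate matters.
* ReliefF scores are computed from a full distance matrix
  ($O(n^2 d)$ memory/time), comfortable for benchmark-scale datasets
  (hundreds of records) but not for tens of thousands.
* The SFS wrapper refits a forest per candidate per step; with all 365
  features and no `cap` this is an overnight computation, by design of
  the wrapper approach rather than of this implementation.
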