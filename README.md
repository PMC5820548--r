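# lectinpred

Sequence-based prediction of cancerlectins — lectins (carbohydrate-binding
proteins) implicated in cancer processes — from protein primary structure.
`lectinpred` is aimed at computational biologists who want to train and
evaluate such predictors, or reuse its building blocks for other binary
protein-classification problems, without leaving R.

The package implements a complete prediction workflow:

1. **Multiview feature encoding.** Each protein sequence is mapped to a
   365-dimensional vector from four complementary views:
   - **CTD** (147): composition, transition and distribution descriptors
     over seven physicochemical groupings of the 20 amino acids
     (hydrophobicity, van der Waals volume, polarity, polarizability,
     charge, secondary structure, solvent accessibility). Composition is
     (N₁/L, N₂/L, N₃/L); transition counts group-crossing dipeptides
     (N_{αβ}+N_{βα})/L; distribution records the relative positions of the
     first, 25%, 50%, 75% and 100% quantile residues of each group.
   - **PseAAC** (70): classical pseudo amino acid composition with λ = 50
     sequence-order correlation tiers θ_j (built from standardized
     hydrophobicity, hydrophilicity and side-chain mass) and weight
     w = 0.15, jointly normalized so the 20 + λ components sum to 1.
   - **PSSM** (120): evolutionary features from a PSI-BLAST
     position-specific scoring matrix, sigmoid-scaled via 1/(1+e^{−x}):
     the 20 per-residue column means (PSSM-AAC) plus the 20 × γ lagged
     autocovariances (PsePSSM, γ = 5).
   - **Disorder** (28): summaries of a per-residue intrinsic-disorder
     track (mean/SD, disordered and ordered segment counts and min/max
     lengths at threshold 0.5, and per-amino-acid mean disorder).
2. **SMOTE class balancing**: synthetic minority points drawn on segments
   between a minority sample and one of its k = 5 nearest minority
   neighbours, until classes are equal.
3. **Two-step feature selection**: a ReliefF relevance filter (keep
   score > 0) followed by a sequential-forward-selection wrapper that
   greedily maximizes 5-fold cross-validated Random-Forest accuracy.
4. **Evaluation**: stratified 5-fold cross-validation with sensitivity,
   specificity, accuracy, Matthews correlation coefficient
   MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)), and ROC/AUC
   from out-of-fold vote fractions.

A synthetic-data generator produces labelled FASTA files with matching
PSI-BLAST-format PSSMs and disorder tracks, so the entire pipeline runs
and is tested fully self-contained.

## Worked example

```r
library(lectinpred)

# a self-contained labelled dataset: FASTA + PSSMs + disorder tracks
sim <- simulate_dataset(n_pos = 40, n_neg = 50, separation = 0.12,
                        disorder_mean = c(0.52, 0.48), seed = 7)

features <- encode_dataset(sim$records,
                           pssm_dir = sim$pssm_dir,
                           disorder_dir = sim$disorder_dir)
dim(features)
#> [1]  90 367     # id + label + 365 features

balanced <- smote_balance(features, k = 5, seed = 7)
table(label = balanced$label, synthetic = balanced$synthetic)
#>      synthetic
#> label FALSE TRUE
#>     0    50    0
#>     1    40   10   # 10 synthetic minority rows restore 50/50 balance

sel <- select_features(balanced, relief_k = 10, cap = 5, trees = 60, seed = 7)
head(sel$ranking, 3)
#> # A tibble: 3 × 4
#>   feature             score  rank retained
#>   <chr>               <dbl> <int> <lgl>
#> 1 diso.mean           0.208     1 TRUE
#> 2 hydrophobicity.C.g3 0.154     2 TRUE
#> 3 polarity.C.g1       0.135     3 TRUE

report <- cross_validate(balanced[, c("id", "label", "synthetic", sel$selected)],
                         classifier = "rf", trees = 100, seed = 7)
report
#> <eval_report> rf, 5-fold CV (smote = off, seed = 7)
#>   Sn 0.940  Sp 0.920  Acc 0.930  MCC 0.860  AUC 0.977
```

The ReliefF ranking surfaces the features that actually separate the
simulated classes (mean disorder and hydrophobic-group composition — the
two signals the generator plants), and the pooled 5-fold metrics quantify
how well the 5 selected features classify: 94% of positives and 92% of
negatives recovered, MCC 0.86.

`autoplot(report)` draws the ROC curve, `autoplot(sel$trace)` the
accuracy-versus-features selection curve, and `tidy()`/`glance()` return
per-fold and one-row summaries. `run_pipeline()` chains all stages and
writes every intermediate (features.csv, balanced.csv, relief.tsv,
sfs_trace.tsv, report.json, roc.tsv, plots, manifest.json) into a run
directory; the same stages are scriptable from a shell via
`inst/cli/lectinpred.R` (subcommands `simulate`, `encode`, `balance`,
`select`, `train-eval`, `run`).

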