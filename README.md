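# pepstack

Stacked ensemble classification of anticancer peptides (ACPs) from
amino-acid sequence, with optional evolutionary-profile features.

## The problem

Anticancer peptides are short (typically 5–50 residue) sequences that
selectively disrupt cancer-cell membranes, and screening candidate
peptides experimentally is slow and expensive. Sequence-based
classifiers fill the gap, and their performance hinges on feature
representation: no single encoding captures composition, sequence
order, physicochemistry and evolutionary conservation at once.

`pepstack` implements a two-stage stacked ensemble over a bank of
**19 feature encodings** in four families:

| family | encoders | dim (defaults) |
|---|---|---|
| amino-acid composition | k-mer, distance residue pairs (DR), reduced-alphabet distance pairs | 400 / 1220 / 602 |
| physicochemical autocorrelation | AC, CC, ACC, PDT over an 8-index panel | 16 / 112 / 128 / 16 |
| pseudo amino acid composition | PC-PseAAC, SC-PseAAC and general variants | 24 / 28 / 24 / 52 |
| profile-based (need PSSMs) | Top-n-gram, PDT-profile, DT, AC/CC/ACC-PSSM, PSSM-DT, PSSM-RT | 20 … 800 |

Stage 1 fits one gradient-boosted tree model per encoding; the vector
of k positive-class scores (k = 19 with profiles, 11 without) is the
**meta-feature vector**. Stage 2 is an RBF-kernel SVM tuned by
exhaustive grid search (C ∈ 2^−5..2^15, γ ∈ 2^−15..2^3, internal
stratified 5-fold accuracy) that produces the final ACP/non-ACP call:

    x_meta[m] = P̂_m(ACP | F_m(peptide)),  m = 1..k
    ŷ = SVM(x_meta) ≥ 0.5

The core encodings are transcriptions of the standard formulas, e.g.
auto covariance at lag d of index u,
`AC(u,d) = Σ_i (I_u(R_i) − Ī_u)(I_u(R_{i+d}) − Ī_u) / (L−d)`,
and PC-PseAAC, `x_u = f_u / (Σf + wΣθ)` with λ sequence-order
correlation tiers θ_j; see the methods vignette
(`vignettes/stacked-acp-classification.Rmd`) for every formula,
default and design decision.

The package also ships the evaluation protocol used in this
literature — Sn/Sp/Acc/MCC, ROC/AUC, repeated stratified k-fold
cross-validation, the DeLong test for paired ROC curves with
better/equal/worse comparison triplets — and a synthetic peptide/PSSM
generator so everything is testable without external downloads.

## Worked example

```r
library(pepstack)

# a labeled benchmark: 120 ACP-like vs 120 background peptides
train <- simulate_peptides(n_pos = 120, n_neg = 120, effect = 0.3, seed = 42)
test  <- simulate_peptides(n_pos = 30,  n_neg = 30,  effect = 0.3, seed = 43)

fit <- pepstack(train, stage1_mode = "out_of_fold", seed = 7)
fit
#> Stacked peptide classifier
#>   encoders: k = 11 ( 3/4/4/0 )
#>   stage 1: out_of_fold gradient-boosted trees, 100 rounds
#>   stage 2: svm (C = 32, gamma = 0.5)
#>   trained on 240 peptides ( 120 ACP / 120 non-ACP )

predict(fit, test) |> head(4)
#> # A tibble: 4 × 4
#>   id    score label note
#>   <chr> <dbl> <chr> <chr>
#> 1 acp1  0.779 ACP   <NA>
#> 2 acp2  0.810 ACP   <NA>
#> 3 acp3  0.827 ACP   <NA>
#> 4 acp4  0.805 ACP   <NA>
```

`k = 11 ( 3/4/4/0 )` says the bank used the 11 sequence-only encoders
(no PSSMs attached, so the 8 profile encoders are dropped); the
`score` column is the stage-2 positive-class score in [0, 1] and
`label` applies the 0.5 threshold. Held-out metrics:

```r
preds <- predict(fit, test)
m <- classification_metrics(confusion_counts(test$label, preds$label))
m$AUC <- roc_auc(preds$score, test$label)
m
#> # A tibble: 1 × 6
#>      Sn    Sp   Acc   MCC mcc_undefined   AUC
#> 1     1     1     1     1 FALSE             1
```

All 60 held-out peptides are called correctly — the planted class
signal (`effect = 0.3`) is strong at this training size. The
stability protocol, repeated stratified cross-validation:

```r
cv_pepstack(train, k = 5, repeats = 3, seed = 7)
#> 3 x 5-fold stratified cross-validation (in_sample stage 1, svm stage 2)
#>   AUC  0.9898 (sd 0.0007)
#>   Acc  0.9764 (sd 0.0020)
#>   MCC  0.9529 (sd 0.0039)
#>   Sn   0.9694 (sd 0.0039)
#>   Sp   0.9833 (sd 0.0000)
```

Real data enter through `read_peptide_dataset("acp.fa", "non_acp.fa")`
(or `read_fasta()` + `attach_labels()`), are filtered by
`validate_peptides()` — sequences with any non-natural residue are
removed and reported — and PSI-BLAST ASCII PSSMs attach via
`attach_pssms(d, dir = "pssm/")` to enable the full 19-encoder bank.
`tidy(fit)` gives per-encoder dimensions and channel AUCs,
`glance(fit)` the selected SVM parameters, `autoplot()` displays ROC
curves, CV distributions and dataset summaries. A command-line front
end for `simulate`, `encode`, `train`, `predict` and `evaluate` lives
at `inst/cli/pepstack.R`.

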