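---
title: "Stacked ensemble classification of anticancer peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble classification of anticancer peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model, its assumptions, the parameters that matter,
the synthetic benchmark, and the places where the design was genuinely
open and a choice had to be made.

## The model

A peptide is a string $P = R_1 R_2 \cdots R_L$ over the 20-letter
amino-acid alphabet. The classifier is a two-stage stack:

1. **Feature bank.** Each peptide is encoded by an ordered bank of
   $k$ feature encodings $F_1, \dots, F_k$ (19 by default: 3
   composition, 4 autocorrelation, 4 pseudo amino acid composition,
   8 profile-based; 11 when no PSSMs are available). The encodings
   deliberately span different views of the sequence — residue usage,
   bounded-distance pair statistics, physicochemical signal structure,
   sequence-order correlation, and evolutionary conservation.
2. **Stage 1.** One gradient-boosted tree classifier is fitted per
   encoding on the training labels. Its positive-class probability is
   that encoding's *meta-feature*; a peptide becomes the vector
   $(\hat p_1, \dots, \hat p_k) \in [0,1]^k$.
3. **Stage 2.** An RBF-kernel SVM on the meta-feature vectors makes
   the final ACP/non-ACP call, with cost and kernel width selected by
   exhaustive grid search under internal stratified 5-fold accuracy.

The stacking assumption is that disagreement among heterogeneous
feature views carries information that a single concatenated feature
space would bury: stage 1 compresses each high-dimensional view into
one calibrated score and stage 2 learns how to weigh the views.

### Stage-1 scoring modes

The classical construction trains each stage-1 model on the full
training set and scores *the same rows* to build the stage-2 training
matrix (`stage1_mode = "in_sample"`, the default). Those scores are
optimistic — a boosted tree ensemble can nearly memorize its training
labels — so the stage-2 grid search sees an easier problem than it
will face at test time. The package therefore also implements
`"out_of_fold"`: each training row is scored by a model fitted on an
internal stratified 5-fold partition that excludes it, and every
stage-1 model is then refitted on all rows for deployment. Out-of-fold
meta-features are honest and give well-spread test-time scores (the
in-sample mode tends to select a very flat SVM whose scores hug 0.5);
measured on the synthetic benchmark, however, the in-sample stack's
held-out *ranking* (AUC) is at least as good, so fidelity and
performance agree on the default. Use `"out_of_fold"` when the score
values themselves matter, e.g. for ranking candidates for synthesis.

The meta-features are stage-1 *probabilities* by default, preserving
each channel's confidence; `stage1_output = "label"` switches to hard
0/1 stage-1 calls for experiments probing how much the confidence
information contributes.

### Second layers

`"svm"` is the default; `"logistic"`, `"naive_bayes"`,
`"decision_tree"`, `"random_forest"` and `"adaboost"` are available
for classifier-comparison experiments. AdaBoost is a compact discrete
SAMME boosting over depth-1 decision stumps implemented in the
package; the others call the standard R implementations.

## The encoders and their parameters

All sequence positions are 1-based in the formulas below; every
encoder validates its length precondition and errors per sequence
(with the offending id) rather than silently adjusting parameters,
because per-sequence parameter changes would make feature dimensions
inconsistent across a dataset.

**k-mer** (`k = 2`, dim $20^k$): frequencies of the $L-k+1$ windows,
lexicographic layout. **DR** (`dmax = 3`, dim $20 + 400\,d_{max}$):
counts of ordered residue pairs $(R_i, R_{i+d})$ per distance block,
the monomer counts forming the $d=0$ block so `dmax = 0` degenerates
cleanly. **Distance pairs** (`dmax = 3`): the same counting scheme on
a clustered alphabet; the bundled `cp13`/`cp14`/`cp19`/`cp20`
alphabets are classical physicochemical clusterings of decreasing
coarseness (`cp20` is the identity and reproduces DR exactly).
Defaults follow the settings common for these descriptors on short
peptides; block-wise normalization divides each distance block by its
own pair total.

**Autocorrelation** (`dmax = 2`): for a physicochemical index $u$
standardized to mean 0 and unit *population* standard deviation over
the alphabet,

$$AC(u,d) = \frac{1}{L-d}\sum_{i=1}^{L-d}
  (I_u(R_i) - \bar I_u)(I_u(R_{i+d}) - \bar I_u),$$

with $\bar I_u$ the per-sequence mean; $CC(u,v,d)$ is the analogous
cross term for ordered index pairs $u \neq v$ and ACC concatenates
both blocks. PDT replaces the product with a squared difference. The
default panel holds eight classical scales (hydrophobicity,
hydrophilicity, side-chain mass, polarity, polarizability, net charge,
solvent accessibility, flexibility), user-replaceable via
AAindex-style flat files. `dmax = 2` respects the shortest admissible
peptides (L = 5); standardized rather than raw index values are used
throughout so that indices on wildly different scales contribute
comparably — the AC formula itself is silent on this, and the choice
is recorded here because the same standardized tables feed PseAAC.

**Pseudo amino acid composition** (`lambda = 4`, `w = 0.05`): the
composition $f_u = n_u / L$ augmented with sequence-order correlation
tiers,

$$x_u = \frac{f_u}{\sum_i f_i + w\sum_j \theta_j} \;(u \le 20), \qquad
  x_{20+j} = \frac{w\,\theta_j}{\sum_i f_i + w\sum_j \theta_j}.$$

Parallel tiers average squared differences of standardized
hydrophobicity, hydrophilicity and side-chain mass
($\Theta(R_i,R_j) = \frac{1}{3}\sum_p (p(R_i) - p(R_j))^2$); series
tiers are per-property products $h(R_i)\,h(R_j)$, laid out lag-major
(both properties at lag 1, then lag 2, …). The general variants accept
any ordered property set and default to the full 8-index panel so they
genuinely differ from the classical encoders. $\lambda = 4$ is the
largest tier order admissible for 5-residue peptides and $w = 0.05$ is
the canonical weight. Parallel-mode vectors provably sum to 1; series
products can be negative, and a normalizer $\le 0$ (reachable only at
large $w$) raises an error naming the sequence rather than returning a
sign-flipped vector.

**Profile encoders** (`dmax = 2`, `n = 1`): a PSSM is an $L \times 20$
score matrix from PSI-BLAST. Scores map to a row-stochastic frequency
profile via the bounded logistic transform $f = 1/(1 + 2^{-s})$
followed by row renormalization — a monotone, documented choice made
because the ASCII PSSM format does not state one (files that already
contain frequencies can be wrapped directly). Top-n-grams take the $n$
highest-frequency residues per row (ties alphabetical); DT counts
Top-n-gram pairs at bounded distances; PDT-profile averages squared
row differences; AC/CC/ACC-PSSM treat the 20 profile columns as
property signals; PSSM-DT accumulates
$\sum_i f(i,a)\,f(i+d,b)/(L-d)$. **PSSM-RT** is only gestured at in
the literature this package draws on; the implementation here is an
explicit stand-in: binarize scores at a threshold (default 0, i.e.
above background) and count co-activated ordered residue pairs per
distance, normalized by $L-d$. It preserves the
residue-relationship intent while being exactly testable, and users
should treat it as this package's definition. Profiles are optional
inputs; the package never runs PSI-BLAST, and without profiles the
pipeline runs the 11 sequence encoders and says so.

On an exactly one-hot profile every profile encoder collapses to its
sequence counterpart (Top-1-gram to composition, DT and PSSM-DT to the
DR pair blocks), which the test suite uses as a master consistency
check.

## Learners and numerical choices

Stage 1 uses xgboost's gradient-boosted trees at library defaults with
100 boosting rounds, single-threaded for bit-reproducibility; the
boosted-tree learner is a standard component here, not a contribution
of the package. Stage 2's SVM grid is the classical log-scale lattice
$C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ (step $2^2$); accuracy
ties resolve to the earliest grid point (smallest $C$, then smallest
$\gamma$), favoring the flattest model among equals. The SVM's
positive score is the signed margin through a logistic link rather
than Platt scaling: libsvm's internal probability calibration is not
seed-controllable from R and would break the package's determinism
contract, while the logistic margin is deterministic, monotone in the
decision value (so AUC is unchanged) and thresholds at 0.5 exactly on
the separating hyperplane. The decision threshold 0.5 assumes roughly
balanced classes, as in the curated benchmarks this tool targets;
it is configurable for screening settings with asymmetric costs.

Cross-validation is stratified (at n of a few hundred, unstratified
folds can easily lose a class); within a repeat, fold confusion counts
are pooled before computing metrics (micro-averaging — stable for
small folds) and the AUC pools all out-of-fold scores. Repeated CV
draws fresh folds per repeat from a per-repeat seed (`seed + r`).
Reported spreads are population standard deviations; a single repeat
reports sd 0 by convention. MCC with a zero marginal is reported as 0
with an explicit `mcc_undefined` flag. The DeLong test uses placement
values with midrank tie handling and a two-sided normal reference; a
degenerate variance (identical score vectors) returns p = 1 with a
flag rather than NaN.

Every random operation (generation, folds, learners) is driven by an
integer seed, and two runs with the same seed produce identical
predictions — a contract the test suite enforces.

## The synthetic benchmark

`simulate_peptides()` emulates a curated ACP benchmark: `n_pos = 200`
vs `n_neg = 200` (the scale of real curated sets), lengths uniform on
5–50 (the band containing most curated anticancer peptides),
negatives i.i.d. from a uniform residue background. Positives carry
two signal channels, both scaled by a single effect size
$\delta \in [0,1]$ (default 0.3):

- **composition** — each residue is, with probability $\delta$, a draw
  from an enrichment target instead of the background. The default
  target is a point mass on lysine, the hallmark cationic residue of
  membranolytic ACPs; concentrating the target keeps $\delta$ directly
  interpretable as the expected excess fraction of the hallmark
  residue, whereas spreading the same $\delta$ over many residues
  dilutes the per-residue evidence until even the Bayes-optimal
  classifier is mediocre on 5-residue peptides. The target is a
  user-settable probability vector.
- **order** — a periodic KLAK-like motif (the amphipathic repeat of
  designed lytic peptides) overwrites each position with probability
  $\delta$, in a fixed phase, creating signal that only
  order-sensitive encoders can exploit.

At $\delta = 0$ both channels vanish and the classes are exchangeable
(a label-blind chi-square on per-class residue counts rejects at its
nominal level — a calibration the tests check). At the default
$\delta = 0.3$ the stack's stratified 5-fold CV accuracy and AUC on
200/200 peptides sit in the high 0.9s while label permutation drops
accuracy to chance; the acceptance script recomputes these numbers.
Matching PSSMs come from `simulate_pssms()`: each profile row is a
Dirichlet draw with concentration $1 + s\,e_{R_i}$ (a unit pseudo-count
everywhere plus sharpness $s$ on the true residue), so $s \to \infty$
recovers the one-hot profile and small $s$ mimics shallow-alignment
noise; scores are written by the exact inverse of the read transform so
files round-trip.

What the generator does **not** emulate: real amino-acid background
frequencies (uniform by default, replaceable), homology structure
between peptides (real benchmarks are redundancy-reduced; simulated
peptides are i.i.d.), true evolutionary profiles (the Dirichlet noise
is position-independent), and any biology beyond the
cationic/amphipathic caricature. Passing the synthetic benchmark
demonstrates that the machinery recovers planted structure of the kind
ACPs exhibit — it does not certify performance on real benchmark
datasets, which additionally depends on dataset curation and on
encoder parameters this literature leaves unstated.

## Problem sizes used in the checks

The test suite verifies every sequence encoder against independent
brute-force transcriptions on 200 random peptides, profile/sequence
consistency on 100 one-hot profiles, DeLong calibration on 2,000
equal-AUC simulations (type-I error within 0.05 ± 0.02 and a KS
uniformity check), and the full-stack benchmark at 200/200 with one
5-fold CV plus a 30× repeated-CV stability run — sizes chosen so the
whole suite completes in minutes on a single core while keeping the
Monte Carlo tolerances meaningful.

## Known limitations

- The in-sample stage-1 default leaks training labels into stage 2;
  it is kept as the faithful default and documented, with
  `out_of_fold` one argument away.
- Encoder parameters (k, distance caps, λ, w, index panels, reduced
  alphabets) for the published ACP models are not recorded anywhere in
  the source literature; the defaults here are the cited descriptors'
  conventional settings for 5–50-mer peptides, and all are
  configurable.
- PSSM-RT is this package's explicit reconstruction of a
  one-sentence description.
- No homology reduction is performed (curated inputs are assumed
  pre-processed); length outliers (> 50) are kept and only reported
  in the dataset summary.
- Scores from the default in-sample mode cluster near 0.5 and should
  not be read as probabilities; use out-of-fold mode or an external
  calibration when probability estimates matter.
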