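---
title: "Methods: feature-based CpG-island methylation classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based CpG-island methylation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgimeth)
```

# Overview

`cgimeth` predicts the binary methylation state of CpG islands from
genomic and epigenomic context. The pipeline has four stages: (1) label
islands from per-CpG or per-probe methylation measurements, (2) compute a
fixed-schema numeric feature vector per island, (3) train and evaluate
binary classifiers (or a support vector regressor for quantitative
predictions) under repeated stratified cross-validation, and (4) predict
unknown islands with a grid-tuned RBF SVM and a per-mille certainty
score. This vignette documents the model, its assumptions, the tunable
parameters, the numerical conventions, and what the synthetic fixtures do
and do not establish.

# Labeling model

Bisulfite amplicon data give a methylation fraction per CpG; overlapping
amplicons covering the same CpG are averaged (unweighted — coverage depth
is not modeled, because input tables do not carry it). The island
fraction is the unweighted mean over its covered CpGs, and the island is
called *methylated* iff that fraction is strictly greater than the
threshold `0.60`. The strict inequality matters only at the exact
boundary: a fraction of exactly 0.60 is unmethylated, and the boundary is
covered by a regression test.

Probe-style data (e.g. 0/1000-scored sequence regions) are mapped to
islands by interval overlap: an island's value is the mean rescaled score
of all overlapping probes, a probe spanning two islands contributes to
both, probes hitting no island are discarded (and counted), and islands
with no probe are excluded (and counted). Because a half-methylated
island cannot be assigned a confident binary state, islands with
fractions in the closed interval `[0.40, 0.60]` are then removed; both
bounds are inclusive, again fixed by boundary tests. Scales are
auto-detected only for values in `[0, 1]` and `[0, 1000]`; anything else
must be declared, avoiding silent unit errors.

Datasets whose minority class falls below 35 instances trigger a warning
(not an error): stratified 10-fold cross-validation becomes unreliable at
roughly that size, which is also why severely imbalanced cell types are
usually dropped from training.

# Analysis window and coordinates

All internal coordinates are 0-based half-open; BED input is read
verbatim, GTF-like input is converted on read. Each island is extended by
the primer length plus 500 bp on both sides (clipped at chromosome
bounds) into its *analysis window*, which captures flanking effects such
as nearby transcription-factor sites. Sequence-composition classes
(attributes, di-/tetranucleotides), DNA structure and conservation are
computed on the un-extended island; motif scans and histone signal use
the window; periodic and closest-CpG statistics use the CpGs lying inside
the island proper. `N` bases are excluded from base counts and break any
k-mer or octamer window rather than being imputed.

# Feature classes

The reference schema has 948 features in 15 classes (in order): TSS
distances 4, island attributes 7, genomic attributes 11,
repeat/Alu-Y/self-alignment 19, SNP 8, periodic CpG 15, closest CpG 6,
dinucleotides 16, tetranucleotides 257, CpG flanks 4, splice sites 5,
TFBS 457, DNA structure 43, conservation 4, histone 92. Feature order is
fixed (classes in the order above, k-mers lexicographic) so sparse
svmlight output is deterministic.

Conventions worth calling out:

* **Ratios.** Observed/expected CpG ratio is `#CpG * N / (#C * #G)` with
  a guarded 0 when the denominator vanishes. CG/TG and AT/CG ratios use a
  `+1` pseudocount in the denominator so degenerate sequences stay
  finite. "CG ratio" is defined here as `#CpG / (N/2)` (the fraction of
  dinucleotide slots occupied by CpG); the term has no unique standard
  definition, so this one is fixed and documented. The both-strand CG/TG
  ratio counts `#TG + #CA` on the forward string, since CA is the reverse
  complement of TG and CG is self-complementary.
* **Distances.** All island-centric distances are measured from the
  island midpoint. "No neighbor" cases use a finite sentinel — the search
  radius for windowed searches (±400/±900 bp), the chromosome length for
  global ones, the window length for within-island CpG statistics — never
  `Inf`/`NaN`, keeping vectors SVM-friendly.
* **Closest CpGs.** Every island CpG contributes the distances to its
  three nearest neighbors; the class emits the three smallest pooled
  values plus the rank-1/2/3 means. With fewer than four CpGs the pooled
  minima are padded with the largest pooled value and an empty rank falls
  back to the previous rank's mean, so a two-CpG island at distance *d*
  emits *d* six times. This decomposition is one of several that yield
  six features; it is fixed here and covered by tests.
* **Windows for SNP features** are ±400 and ±900 bp, mirroring the repeat
  windows; the choice is configurable and kept symmetric for lack of a
  canonical one.

## Motif scoring

All motif classes share one weight-score scanner. A frequency PFM is
turned into an additive matrix `log2((f + eps)/bg)` with `eps = 0.01`;
ratio PFMs (methylated/unmethylated flank quotients) contribute
`log2(R)` directly. The score of a window is the sum over its bases; both
strands are scanned and the per-position maximum of the two orientations
is used (a symmetric choice; strand handling is not otherwise
determined). Windows containing `N` are skipped entirely. On this scale a
score of about 5 marks a good match — that is the default hit threshold
`theta` — and matrices that never reach a score of 1 on the training
sequences are removed from the TFBS library as insignificant. The
background model stands in for a genome-frequency significance
correction; it reproduces the same "≥5 is good" scale and is the
documented approximation.

Flanking models divide a column-stochastic PFM of methylated-CpG flanks
by one of unmethylated-CpG flanks (pseudocount 0.01 per count cell before
normalization), at flank sizes 4 and 20 bp, once cell-type-specific and
once from a generic reference set (falling back to the same records when
no separate reference exists). The island feature is the maximum score
over its CpG-centered flank windows in forward orientation, since the
models are built from forward-strand contexts.

# Classifiers and scoring

Labels enter as a factor with *methylated* as positive class. Features
are z-scored with training-fold statistics only; the transform is stored
in the model and re-applied at prediction (no leakage into held-out
folds). Seven algorithms are registered — SVM RBF and linear (libsvm via
e1071, the canonical implementation), random forest, kNN, decision tree
(rpart), naive Bayes, and `kstar`, a small instance-based learner with
exponential distance weighting in the spirit of entropic instance-based
classification. Each exposes a real-valued decision score oriented so
positive means methylated; for probability-based learners the score is
`p − 0.5`.

Scores: `ACC = (TP+TN)/n`; `MCC = (TP·TN − FP·FN)/sqrt((TP+FP)(TP+FN)
(TN+FP)(TN+FN))` with the 0/0 → 0 convention, so a constant classifier on
a 71%-negative set has ACC 0.71 but MCC 0; AUC is the midrank
Mann–Whitney statistic (ties count ½, single-class fold → `NA`, excluded
from aggregation); regression uses `AAE = mean |actual − predicted|`.
MCC is the headline metric because island data are imbalanced.

Evaluation is stratified k-fold cross-validation (k = 10) repeated 10
times with derived seeds; the 100 per-cell scores are averaged and
reported with their standard deviation, and the whole procedure is
reproducible from one master seed. Stratification is applied to the CV
folds as well as to validation splits — it stabilizes fold compositions
on small, imbalanced sets.

## Grid search

RBF hyperparameters are selected on a log2 grid, C over `2^-5 … 2^15`,
gamma over `2^-15 … 2^3`, exponent step 2 (bounds configurable). Each
point is scored by repeated CV — 5-fold × 2 repetitions by default inside
the grid, a deliberate economy since the final model is re-evaluated with
the full 10×10 — on the selection metric, MCC by default; a hook
accepting `(ACC, MCC, AUC)` allows any combined score, and MCC is the
default because combined selection scores track maximal MCC in practice.
If the best point lies on a grid border the grid is extended two steps in
that direction (up to three times); once a peak is interior, the step is
halved around it. Failed points (non-finite scores) are excluded from the
argmax; exact ties resolve to the smallest (C, gamma) in scan order, a
deterministic tie-break.

Predictions report labels plus a per-mille certainty:
`round(1000·|d_i| / max_j |d_j|)` over the predicted batch, 0 when all
decision values are 0. The score is relative to its batch by definition,
so certainties from different prediction runs are not comparable.

# Synthetic fixtures

The generator emulates the pipeline's input universe: a background genome
drawn i.i.d. with genome-like base frequencies and 80% of background CpGs
depleted (G→A), islands overwritten as GC-rich segments with planted CpGs
every 6–18 bp (optionally 9-periodic in methylated islands), per-CpG
beta-distributed methylation values (mean ≈ 0.8 methylated / 0.2
unmethylated, re-drawn until the island mean clears the 0.60/0.40 bands
so emitted truth labels and the labeling module agree exactly), genes
with TSS near unmethylated islands, SNP/repeat/self-alignment/conservation
tracks, 23 histone bedGraphs in which methylated islands receive a
configurable mean shift (default +2 sd, the planted study condition), a
456-matrix TFBS library (random count PFMs plus a few consensus matrices
lifted from island sequence so the significance filter keeps some), four
splice-site PFMs and a 43-parameter octamer table with a `*` default row.
Each file type has its own RNG stream derived from the master seed, and
output is byte-identical per spec.

What passing tests on fixtures establish: correctness of every
computation against independent oracles, exact protocol behavior, and
that the learning stack recovers a planted signal of known size while
honest nulls (zero shift, permuted labels) stay near MCC 0. What they do
not establish: performance on real epigenomes — real histone signal is
noisier and correlated across marks, real sequence composition is not
Markov-0, and real methylation is bimodal but not beta-clean. Fixture
results are an engineering control, not a biological benchmark.

Problem sizes used by the test suite and the acceptance script are chosen
to exercise the contract at desk scale: 12-island fixtures with a reduced
PFM library for module tests, a 6-island fixture under the full reference
configuration (456 PFMs) for the 948-feature layout check, and a
200-island, 4-chromosome fixture for signal recovery with grid search and
10×10 CV.

# Known limitations

* Annotation ingestion is file-based (BED/bedGraph/GTF-like/JASPAR text);
  there is no liftover, no remote database access and no BAM/CRAM path.
* The octamer structure table is an input; the package computes windowed
  means over it but does not re-derive structural energies.
* The TFBS significance filter is frequency-based, not a calibrated
  p-value; the `kstar` learner approximates the spirit, not the letter,
  of entropic instance-based classification.
* Leave-one-out CV is intentionally absent; repeated stratified k-fold is
  the only evaluation protocol.
* Certainty scores are batch-relative per prediction run.
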