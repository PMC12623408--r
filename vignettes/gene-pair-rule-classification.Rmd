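---
title: "Gene-pair-rule classification of cell type of origin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair-rule classification of cell type of origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Verifying what kind of cell a transcriptome came from is a recurring need:
cell lines drift or are mislabeled, public cohorts mix platforms, and
single-cell atlases annotate types that bulk studies never sorted. The
obstacle to pooling many studies into one training set is that absolute
expression values are not comparable across platforms and library
preparations, and explicit batch correction of heterogeneous public data is
itself fragile.

`pairForest` sidesteps normalization entirely. Its only features are binary
**gene-pair rules**: within one sample, is the expression of gene *A*
strictly smaller than the expression of gene *B*?

$$ r_{AB}(x) \;=\; \mathbf{1}\left[\,x_A < x_B\,\right] $$

A rule looks at a single sample at a time, so its value is unchanged by any
strictly increasing transform applied to that sample — log scaling, TPM
scaling, quantile shifts, or an arbitrary monotone platform response. Merged
matrices are therefore used verbatim: no cross-sample normalization or batch
correction is performed anywhere in the pipeline, and the merging step
(`mergeStudies()`) deliberately guarantees bit-exact pass-through of the
input values.

## The procedure

1. **Gene ranking** (`rankGenes()`). Each sample's values are replaced by
   within-sample ranks (average ranks on ties) and a Random Forest
   (impurity importance, 2000 trees by default) ranks genes two ways:
   *altogether* — one multiclass forest, genes ranked by their ability to
   separate all classes jointly; *one-vs-rest* — one binary forest per
   class. Both views are kept because a gene that splits one rare class from
   everything else can be invisible to the joint ranking.
2. **Gene selection** (`selectTopGenes()`): the union of the top genes of
   every list (defaults 85 altogether + 100 per class; the desk-scale
   pipeline configuration uses 60 + 40 against 400 simulated genes).
3. **Rule generation and evaluation** (`generateRules()`,
   `evaluateRules()`): all unordered pairs of the selected genes, in
   canonical orientation (lexicographically smaller symbol first, since the
   two orientations are complementary bits carrying identical information to
   a tree). Ties evaluate to 0 — the rule is the *strict* inequality.
4. **Rule ranking** (`rankRules()`): the same two importance schemes on the
   binary rule features, with per-sample weights proportional to inverse
   class frequency so that a 10-fold imbalance (which the default synthetic
   design deliberately contains) does not let the majority class dominate
   impurity gains.
5. **Capped selection** (`selectRules()`): a greedy descent through each
   ranked list (defaults 100 altogether + 100 per class) that skips any rule
   which would let either of its genes appear more than
   `geneRepetitionCap` times (default 1). The cap forces rule diversity: no
   single hub gene can carry the classifier, which is also what makes the
   model resilient when genes are missing at prediction time.
6. **Shadow-feature pruning** (`borutaPrune()`): candidate rules compete
   against column-shuffled copies of themselves. In each iteration a rule
   scores a hit when its importance beats the best shadow; after each
   iteration a two-sided binomial test on the hit count (Bonferroni-adjusted
   across the rules still undecided, alpha = 0.01) confirms or rejects
   rules. Rules still undecided when the iteration budget is exhausted are
   kept — the conservative direction, since a false keep costs little while
   a false rejection silently discards signal.
7. **The probability forest** (`trainRuleForest()`): 1000 bagged trees on
   the surviving binary features, grown to purity (`minNodeSize = 1`), with
   inverse-frequency case weights. Scores for a sample are the per-class
   tree-vote fractions; they sum to one and behave like a soft label. A
   sample of genuinely mixed identity receives split scores rather than a
   confident wrong label — the signature read-out for putatively
   misidentified cell lines.

## Prediction with missing genes

Public validation sets rarely contain every training gene; with a gene cap
of 1, losing one gene silences a whole rule. `predictScores()` therefore
evaluates what it can and imputes the rest, with the training rule matrix
stored inside the model so every imputation has an auditable basis:

* `impute_knn` (default): for each query sample, the `kImpute = 5`
  Hamming-nearest training samples over the *evaluable* rules vote on each
  missing rule. Because the fill is conditioned on the sample's own
  surviving evidence, the reconstructed pattern is class-consistent, and
  recovery stays above 0.9 even with half the rule genes deleted (about 75%
  of rules silenced — each rule survives only if both of its genes do).
* `impute_majority`: every missing rule gets its global training-majority
  value. Simple and deterministic, but a constant fill makes every query
  resemble the most common training pattern; with strong class imbalance
  and a majority of rules missing this collapses predictions toward the
  largest class, which is why it is not the default.
* `error`: refuse any missing gene.

A `maxMissingFraction` cap (default 0.75) refuses predictions that would be
mostly imputation. Note that deleting 50% of rule genes at random silences
~75% of rules in expectation, which straddles that default; experiments that
deliberately delete half the genes should raise the cap (the missing-gene
experiment in `scripts/acceptance.R` uses 0.85) rather than reading refusal
as failure.

## The synthetic cohort

All tests and the acceptance experiments run on seeded synthetic data
(`simulationConfig()`, `simulateBulk()`, `simulateMixture()`,
`simulateSingleCell()`); nothing is downloaded. The generator emulates the
features the method must cope with:

* **Cell-type structure**: five classes (astrocyte, endothelial, microglia,
  monocyte, neuron) with disjoint marker blocks of 20 genes elevated by
  `markerEffect = 2` natural-log units over a uniform(1, 4) log baseline —
  a strong but realistic sorted-cell-type contrast.
* **Multi-study batch distortion**: per-study gene-wise log-normal scale
  factors (`batchSigma = 0.5`), so each study measures the same biology
  through its own gene-specific response; samples of each class cycle
  through the 5 studies.
* **Class imbalance**: 32/27/140/13/46 samples (258 total), mirroring the
  kind of skew real multi-study training sets have, and exercising the
  inverse-frequency weighting.
* **Count noise**: negative binomial with dispersion 0.1 at library sizes
  of 200k-500k — the standard RNA-seq count model.
* **Mixtures**: samples drawn from a weighted average (on the linear scale)
  of two class profiles, emulating a heterogeneous or misidentified line.
* **Single-cell mode**: the same profiles at 1k-5k library sizes with
  post-hoc Bernoulli dropout, feeding `aggregatePseudobulk()`.

What it does **not** emulate: gene-gene correlation beyond the marker
blocks, transcript-level or splicing effects, UMI chemistry, ambient
contamination, or platform-specific length biases. Passing tests therefore
demonstrate the pipeline's statistical mechanics — invariance, imbalance
handling, imputation, pruning — not performance on any particular real
cohort; headline accuracies on real data cannot be reproduced without the
original repositories.

**Problem sizes.** The default desk-scale experiment uses 400 genes, 258
samples, 60 + 40 selected genes, 100 + 100 rule quotas at cap 1 (about 60
final rules after pruning) and builds in a few seconds; the same code scales
to the 8–9k-gene regime of real cohorts with the paper-scale defaults of
`selectTopGenes()`.

## Read-origin quality control

A separate concern for cell-line work is whether the reads themselves come
from the expected species. `buildKmerIndex()` stores every canonical k-mer
(k = 25, strand-collapsed to the lexicographic minimum of the k-mer and its
reverse complement) of two references with an A-only/B-only/both flag —
exact hash-set membership; no probabilistic hashing is attempted at toy
scale. `classifyReads()` counts per read the k-mers in each flag class and
applies a declared decision rule: a reference wins with at least
`minHits = 4` specific k-mers and a lead (`margin = 2`) over the other;
`both` requires shared support while neither specific count reaches
`minHits`; too little total support is `neither`; everything else is
`ambiguous`. The rule, including the ambiguous band, is an explicit,
documented surrogate — tools in this space do not publish their exact
per-read tie-breaking.

`estimateRrnaFraction()` flags a read as ribosomal when at least half of its
k-mers occur in an rRNA reference, and uses a shorter k (default 15): a
single substitution destroys up to k consecutive k-mers, so at a 1% per-base
error rate k = 25 pushes a noticeable tail of true rRNA reads below the 0.5
threshold (a two-error 100-mer read can lose half its 25-mers), while at
k = 15 the destroyed fraction stays safely below threshold and random 15-mer
collisions remain negligible. The shared-segment construction in
`makeToyReferences()` reproduces the diagnostic signature this module
exists for: a high cross-species "both" fraction explained by conserved
rRNA rather than contamination.

## Numerical and design choices

* **Ties**: rule ties evaluate to 0 (strict `<`); score argmax ties break
  lexicographically and are flagged (`is_tie`) because a hard label is
  misleading precisely when scores tie.
* **Splits**: stratified, per-class `floor(fraction * n)` with at least one
  sample on each side; a class of size 1 is an error.
* **Confidence intervals**: exact Clopper–Pearson for overall accuracy; the
  no-information rate is the largest class frequency and its p-value is the
  one-sided exact binomial tail — both cross-checked in the test suite
  against an independent reference implementation.
* **Seeding**: every stochastic stage derives its stream from one pipeline
  seed via `stageSeed(seed, stageName)` (a modular string hash kept below
  2^31), so adding a stage never perturbs earlier streams and identical
  (config, seed) pairs reproduce identical artifact checksums, which the
  run manifest records.
* **Serialization**: models round-trip through a single JSON document with
  17 significant digits — verified bit-exact for IEEE doubles — so a
  restored model's predictions are identical to the original's.
* **Optimization criterion**: `optimizeParameters()` scores each grid point
  by out-of-bag macro-averaged balanced accuracy (robust to imbalance) and
  breaks ties toward fewer rules, then fewer trees.

## Known limitations

* Rules are pairwise and marginal: biology expressed only in higher-order
  combinations of more than two genes is invisible to the ranking stages.
* Gene-wise (as opposed to sample-wise) distortions are not provably
  neutral: a platform that inverts the within-sample order of two specific
  genes flips that rule for every sample. The forest's redundancy across
  many rules is the mitigation, not a guarantee.
* kNN imputation assumes the training cohort contains samples resembling
  the query class; a query from a class never trained on is imputed toward
  its nearest trained neighbor, and its split scores must be read as such.
* The read-origin module is exact and in-memory; it targets spot-checks and
  toy references, not genome-scale indexing.
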