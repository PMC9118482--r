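---
title: "nucmeta: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucmeta: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `nucmeta` implements, the
choices made where more than one reasonable design existed, and what the
synthetic benchmarks do and do not establish about real data.

## The data model

A `ProteinRecord` holds one protein's sequence and aligned per-residue
tracks. Experimental tracks: ternary disorder (1/0/NA), 8- and 3-state
secondary structure, absolute and relative solvent accessibility, and
ternary DNA-/RNA-binding flags. Predicted tracks: disorder propensity,
3-state secondary structure, relative accessibility, and DNA-/RNA-binding
propensities from a *disorder-trained* and a *structure-trained* predictor
(the package treats these as inputs; it never runs the upstream tools),
plus optional meta-predictor outputs.

Key invariant: a residue marked disordered carries no experimental
secondary structure or solvent accessibility — disordered regions have no
stable structure to measure, so those values are represented as missing,
never imputed. `validateRecord()` checks the full invariant set and reports
violations rather than throwing, which keeps validation usable as a data
audit; readers and writers refuse invalid records.

The on-disk `track_tsv` dialect is one block per protein (a header line,
then one line per track) with `NA` as the missing sentinel and numeric
values fixed at 3 decimals. The fixed formatting makes output
byte-deterministic and golden-file tests stable; the synthetic generator
quantizes its continuous tracks to the same 3 decimals at creation so that
`readDataset(writeDataset(ds))` reproduces `ds` exactly.

## Annotation processing

* **8→3-state collapse**: H,G→helix; E,B→strand; I,T,S,`-`→coil. The DSSP
  I (π-helix) state is mapped to coil; the 3-state codes themselves are
  accepted and map to themselves, making the collapse idempotent.
* **Relative accessibility**: ASA divided by a residue-specific maximum,
  clipped at 1 because observed ASA can exceed tabulated maxima. The
  bundled table is the theoretical max-ASA set of Tien et al. (2013,
  PLoS ONE 8:e80635); any complete positive table can be supplied, and the
  table in use is data, not code.
* **Chain selection** is position-wise: for each residue of a protein
  sequence, the covering PDB chain is the longest one (chains of ≤30
  residues are peptides and excluded), ties broken by the numerically
  smallest resolution — a chain with no resolution (NMR) loses all
  resolution tie-breaks — then lexicographically for determinism. Different
  portions of one sequence may therefore come from different chains.
* **Disorder from unresolved residues** uses the missing-density
  convention only (no minimum-length filter on the disordered region).

## The meta-model

Inputs are the two binding-propensity tracks for one task (DNA or RNA),
min–max normalized per track with parameters fitted on the pooled residues
of the training split only (global, not per protein: per-protein
normalization would erase between-protein score calibration, and the
combined tracks must live on one common [0,1] scale). Degenerate
(constant) training tracks map everything to 0.5.

The network is a fully connected feed-forward net over a sliding window of
`w` residues from both tracks (input width `2w`; positions beyond the
termini padded with 0, the "no binding evidence" floor of the normalized
scale). Hidden layers use ReLU, the single output unit a sigmoid. Training
minimizes binary cross-entropy with class weights inversely proportional to
class frequency (binding residues are ~5–10% of the pool), using Adam
mini-batch updates (batch 256, learning rate 0.005), an epoch cap of 100
and early stopping when validation AUC has not improved for 10 epochs. Adam
rather than plain SGD keeps convergence robust at this small epoch budget;
all randomness (initialization, batch shuffling) derives from one declared
seed, so training is byte-reproducible.

Hyperparameters are grid-searched: window `w ∈ {1, 3, 5, 7}` × depth 1–3
with nested widths (6), (6,4), (6,4,2). The selected configuration
maximizes validation AUC; exact ties prefer the smaller window, then the
shallower net (the simpler model at equal quality). DNA and RNA binding are
two independently trained single-output models sharing the architecture —
the two tasks are reported separately throughout, and independent heads
keep the tasks from competing for capacity. The 70/30 train/validation
protein-level split is unstratified (stratification was the open
alternative; with hundreds of proteins per class the simple split is
adequate and matches the declared seed semantics).

Serialized models are plain JSON (config, normalization parameters, layer
weights), so a trained model is portable and diffable.

## Evaluation

Residues are pooled across proteins. For a task, positives are the binding
residues of the task's binding proteins; negatives are the non-binding
residues of those proteins plus *all* residues of the
non-nucleic-acid-binding proteins (the pooled-negative convention; the
alternative — only non-NA residues — was considered and rejected because
dataset-level metrics are reported as single values over one pool).
Residues with unknown labels are excluded.

AUC is the Mann–Whitney pair statistic computed from midranks (ties count
half), hence invariant under strictly increasing score transforms. ROC
curves are step functions over the distinct observed scores with the rule
"positive iff score ≥ threshold" and no interpolation; the trapezoidal area
under the step curve equals the pair-statistic AUC exactly. Sensitivity at
an FPR cap is the maximal TPR among operating points within the cap;
specificity at a TPR floor is the maximal specificity among points at or
above the floor. Binary calls standardize thresholds the same way: the
smallest observed score whose reference-negative exceedance rate is within
the FPR cap.

### Significance of differences

Robustness of a difference (between two methods, or two residue groups) is
assessed by repeated protein-level subsampling: `nReps` subsets of a
fraction `f` of the proteins, drawn without replacement (protein-level, so
within-protein correlation is respected; residue-level resampling would
fake independence), with the paired statistics recomputed per subset.
Defaults follow the two analysis families: 50 × 50% for method
comparisons, 100 × 20% for relation contrasts. The paired differences are
tested with a paired t-test when the Anderson–Darling test does not reject
normality at 0.05 and with the Wilcoxon signed-rank test otherwise;
two-sided p-values are reported, and all-zero differences return p = 1 (the
signed-rank statistic is undefined there, and "no evidence of difference"
is the only safe report).

One correction is applied to both branches. Overlapping subsets of one
dataset are not independent replicates: every per-subset difference centres
on the dataset-level difference, so the naive resampled test rejects a
*population* null at a rate set by `nReps` rather than by the data (with
100 × 20% resampling, a chance dataset-level difference of one standard
error is declared significant almost always). The t branch therefore uses
the Nadeau–Bengio subsampling-corrected standard error
`s·sqrt(1/n + f/(1−f))`; the signed-rank branch applies the plain test to
variance-inflated differences `mean(d) + (d − mean(d))·sqrt(n(1/n + f/(1−f)))`
— inflating the spread rather than deflating the rank statistic, because a
rank statistic saturates once all signs agree and would otherwise be unable
to distinguish a large effect from a marginal one. With this correction the
machinery is calibrated: on generator configurations with no built-in
association the contrast reaches 0.05 at roughly the nominal rate, while
the built-in effects (coil-enriched disorder, exposure-lifted binding,
strand-depleted binding, method differences of Table-2 magnitude) remain
significant. This is the package's main deliberate departure from the naive
resampled test, which answers only the weaker question "is the sign of the
observed difference stable across subsets of this dataset".

## Relation analyses

Six characteristic pairs are supported; each can draw either axis from
experimental or predicted tracks, so experimental↔predicted consistency is
a first-class query. The grouping axis is the first name in the pair
(disorder for `disorder_*`, binding for `binding_*`, secondary structure
for `ss_rsa`); group summaries are secondary-structure compositions,
fractions, or five-number percentile summaries (5/25/50/75/95th, linear
interpolation between closest ranks — `quantile` type 7). Undefined
statistics (an empty group, e.g. experimental accessibility of disordered
residues) propagate as `NA`, never as 0, so a missing measurement cannot
masquerade as depletion; their contrasts are reported untested. Predicted
disorder is binarized at propensity ≥ 0.5; predicted binding uses calls at
FPR 0.2 against the dataset-wide reference pool, mirroring how such calls
are standardized in evaluation.

## The synthetic generator

The generator exists so that every analysis is exercisable without any
download. It emulates the statistical structure of curated human-proteome
benchmarks:

* protein classes (DNA-binding / RNA-binding / non-NA-binding) with a
  configurable mix, default (0.3, 0.3, 0.4);
* segmental disorder from a two-state Markov chain (stationary content
  0.20, mean segment 30 residues);
* segmental binding (segments of 3–15 residues) at prevalence 0.07 in
  structured regions and 0.20 in disordered regions — the benchmark-scale
  figures for structure-annotated (~6–8%) and disorder-annotated (~19–26%)
  binding proteins;
* secondary structure at (H, E, C) = (0.38, 0.21, 0.41) for structured
  non-binding residues, a strand-depleted (0.40, 0.07, 0.53) for binding
  residues, and a coil-biased (0.26, 0.08, 0.66) for predicted structure
  inside disordered regions;
* Beta-distributed RSA with state-dependent means (helix 0.30, strand
  0.22, coil 0.45; +0.15 for binding residues) and exposure-lifted
  predictions inside disorder (mean 0.65);
* two binding-propensity tracks `clip(0.2 + 0.4·detectable + N(0, σ))`,
  σ = 0.1 by default. Disordered-region segments are detectable by the
  disorder-trained role, structured-region segments by the
  structure-trained role, and each whole segment becomes detectable by both
  with probability κ (default 0.25). κ is the complementarity dial: κ = 0
  gives fully complementary tracks, κ = 1 fully redundant ones, and the
  consensus gain over the best single track decreases in κ.

Splits: half the proteins are held out as a test pool; the rest are split
70/30 into train/validation, all at the protein level and reproducibly from
the seed.

What the generator does **not** emulate: real amino-acid composition,
homology structure, segmental autocorrelation of secondary structure,
cross-prediction between DNA and RNA tasks, or the error profiles of any
real predictor. Passing tests therefore establish that the algorithms
recover the relations and complementarity structure *they are given*, at
benchmark-like prevalences — not that any particular real predictor pair
behaves this way. Absolute metric values on synthetic data (AUCs near
0.98+ for the consensus under the default signal-to-noise) are higher than
on real benchmarks, where AUCs around 0.6–0.72 are typical; only the
qualitative ordering (min below the single tracks; average/max/meta well
above; meta at least consensus-level) is the tested claim.

## Problem sizes and numerical choices

The test suite and the acceptance script use 300-protein datasets
(~57,000 residues) for calibration and complementarity checks, 5 seeds for
averaged claims, 20 seeds for false-positive-rate claims, and the full
4 × 3 hyperparameter grid for training; the whole suite runs in about two
minutes on one CPU, the acceptance script in under a minute. Other
numerical conventions: residue indices are 1-based everywhere (R-native,
and the convention of sequence viewers); thresholds are always drawn from
observed scores; exact AUC ties during model selection fall back to the
simpler model; RSA clipping and the 0.5 degenerate-normalization value are
stated invariants, asserted both in code and tests.

## Known limitations

* The evaluation pools residues across proteins; per-protein averaging
  (which weights short and long proteins equally) is not implemented.
* The meta-model consumes exactly two input tracks; fusing more predictors
  would require widening the input layer.
* Only the metric suite above is provided — no precision–recall curves,
  MCC or F1.
* The CAID reader covers the per-residue index/residue/propensity/binary
  layout; converters for other deposited benchmark layouts must be written
  against the actual files.
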