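---
title: "Imputing missing contact maps in a biosample-by-assay grid"
author: "contactImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing missing contact maps in a biosample-by-assay grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the
factorization model and its assumptions, the normalization pipeline,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed. Commands are shown unevaluated; the README walks through a
complete run with its printed output.

## The imputation problem

A chromosome-conformation experiment yields, for one biosample and one
assay, a symmetric matrix of contact counts between pairs of fixed-width
genomic bins (here 100 kb by default). Collecting all experiments into a
biosample-by-assay grid, most cells are missing. The package's task is to
predict an entire missing contact map from the observed maps, exploiting
three kinds of sharing: maps from the same biosample share compartment
and domain structure, maps from the same assay share protocol-specific
contact selection, and all maps share the strong decay of contact
frequency with genomic distance.

## Normalization

Each map passes through three steps, in this order:

1. **`log(x + 1)`** on every entry (`log1pMap`). Contact counts span
   orders of magnitude; the shifted log tames the dynamic range while
   mapping zeros to zero.
2. **Marginal-based bin filtering** (`selectRetainedBins`,
   `applyBinMask`). For each *training* map, the marginal (full-matrix
   row sum) of every bin is compared with the map's median marginal; a
   bin further than `kMad = 10` median-absolute-deviations away in any
   training map is removed from every map. Deriving the mask from
   training maps only, and applying it unchanged elsewhere, keeps
   held-out data from influencing any modeling choice; a metamorphic
   test perturbs a validation map and asserts the mask is unchanged.
3. **Fixed-total scaling** (`normalizeTotal`): each map is scaled so its
   entries sum to `total = 1e5`, removing sequencing-depth differences
   between experiments.

Two readings of step 2 are defensible: the deviation statistic can be
the *median* or the *mean* absolute deviation from the median. The
median-based form is the default (`madKind = "median"`) because it is
the robust statistic conventionally paired with a median center; the
mean-based form is one switch away. Similarly, marginals are computed
*after* the log transform because the pipeline is specified as a
sequence and the mask step follows the log step; computing them on raw
counts would make the filter more aggressive on deep experiments. When
a map's deviation statistic is exactly zero (near-uniform synthetic
maps), the filter is disabled for that map rather than discarding every
off-median bin — the degenerate case has no information about bin
quality. The normalization total is the sum over the full dense matrix
including the diagonal; an upper-triangle-only option exists for users
who count each contact once.

## Train/test/validation split

`splitExperiments` processes assays in sorted label order; within each
assay the observed experiments are shuffled with the seeded RNG and
dealt cyclically to train, test, validation, train, test, ... This
guarantees every assay has a training example, and an assay with two
experiments contributes one training and one test map. The per-assay
counts for any assay size follow directly from the dealing rule and are
tested against an independent enumeration for sizes 1–10.

## The factorization model

`ContactModel` holds one embedding table per input axis — biosample,
assay, genomic bin, and bin-pair separation (one row per separation
`0 .. nBins - 1`, indexed raw, not log-binned) — plus a multilayer
perceptron. A query `(b, a, i, j)` is canonicalized to `i <= j`, the
five relevant embedding rows are concatenated, and the MLP emits one
value. Canonicalization *is* the symmetry mechanism: swapping the two
positions produces bit-identical input, hence bit-identical output, and
whole-map predictions (`predictContactMap`) are reflected across the
diagonal so the output matrix equals its transpose exactly.

Defaults (`defaultHyperparams()`): 16 biosample factors, 128 assay
factors, 128 position factors, 128 distance factors, 4 hidden layers of
256 units, dropout 0.4, Adam at initial learning rate 1e-4, batches of
10,000 off-diagonal entries, 526 batches per epoch, up to 50 epochs.
Choices left open by that architecture are resolved conventionally:
rectified-linear hidden activations with a linear output; inverted
dropout after each hidden activation (active only during training);
He-scaled normal weight initialization with zero biases and N(0, 0.1)
embedding entries; Adam with β₁ = 0.9, β₂ = 0.999, ε = 1e-8.

Training (`trainContactModel`) samples batches uniformly with
replacement over (training experiment, unordered off-diagonal pair),
never touching the diagonal. After every epoch the full validation MSE
— all upper-triangle off-diagonal entries of every validation map — is
computed, and the returned model carries the parameter snapshot of the
best-validation epoch (`bestEpoch`), with the whole history retained
(epoch 0 records the random initialization). Because the training
distribution is off-diagonal, validation MSE excludes the diagonal by
default (`valIncludeDiagonal` includes it), and diagonal entries of
predicted maps are flagged in the documentation as extrapolations; they
can be zeroed with `includeDiagonal = FALSE`.

The compute core is compiled (RcppArmadillo) in single precision:
embedding gather/scatter touches contiguous memory, dropout masks come
from a counter-seeded xorshift generator, and validation error is
accumulated in double precision. Training is single-threaded and
bit-reproducible given the seed; the suite asserts two same-seed runs
produce identical histories.

### Convolutional position encoder

An experimental variant (`variant = "conv"`, `convForwardPass`) replaces
each raw position row with a learned reduction of the 21 embedding rows
in a ±10-bin window (zero rows beyond the chromosome ends): a
convolution with one input channel, three output channels, and a kernel
spanning the 21-row window axis, followed by a 3-to-1 channel
combination with a 1×1 kernel. The kernel geometry — consuming the
window axis in one step — is the one interpretation that reduces the
stack in a single pass; it is isolated behind the variant flag. The
variant is provided as a forward-pass encoder for architecture
exploration; the training loop optimizes the standard model, which is
also the better-performing architecture in our hands.

## Baselines

Three mean predictors (`rowMeanImpute`, `columnMeanImpute`,
`crossMeanImpute`) average, elementwise and unweighted, the observed
maps sharing the target's assay, biosample, or either. The target's own
map, if observed, is always excluded; the same-assay and same-biosample
pools are therefore disjoint and the cross pool is their union. When a
split is supplied the pools contain training experiments only — the
fair comparison against a model fit on the training split; without a
split all observed maps qualify, which is the mode used when imputing a
full grid for downstream comparison. Maps are already depth-normalized,
so unweighted averaging needs no read-depth correction.

## Contact-map summaries

* **Contact decay profile**: mean value along each diagonal, `d = 0 ..
  nBins - 1`. The diagonal is included as `d = 0`.
* **Compartment eigenvector**: the unit-norm eigenvector of the map for
  the largest-magnitude eigenvalue, computed on the normalized log map
  itself. An eigenvector's sign is arbitrary, so it is fixed
  deterministically: flipped if its Pearson correlation with the map's
  marginal vector is negative, with ties resolved by making the first
  non-zero component positive — without such a rule, downstream
  correlations of eigenvector profiles would be corrupted at random.
  The conventional A/B-compartment pipeline (divide each diagonal by
  its mean, correlate columns, then decompose) is available via
  `observedExpected = TRUE`; on the raw map of a compartment-only
  synthetic matrix the leading eigenvector tracks overall intensity,
  while the observed/expected form recovers the planted sign pattern,
  which is why the generator tests use it.
* **Insulation score**: the mean of a `window x window`
  diagonal-anchored submatrix slid along the diagonal one bin at a
  time (default window 30 bins), length `nBins - window + 1`. These are
  diagonal-anchored squares, not boundary-crossing windows; dips mark
  domain boundaries, and with `window = nBins` the profile collapses to
  the global matrix mean.

## Evaluation and comparison analyses

`mapMSE` averages squared differences over the upper triangle
(diagonal excluded by default, matching the training distribution).
`perDistanceCorrelation` reports the Pearson correlation along each
diagonal, with undefined distances (fewer than two pairs, or zero
variance in either map) reported as missing rather than zero.
`mseVsSharedTraining` regresses per-map test MSE on the number of
training experiments sharing the assay, the biosample, or either
(ordinary least squares, with zero-variance predictors yielding missing
fits). `hyperparameterSearch` samples configurations uniformly from the
Cartesian grid — without replacement when the grid is large enough —
and trains each; 500 samples is the study-scale default, and tests use
a handful.

`entityCorrelation` compares biosamples (or assays) by the mean Pearson
correlation of their feature profiles over shared assays (or
biosamples). Pairs where either profile has zero variance contribute a
missing value that is excluded from the mean — an undefined correlation
must not silently become zero — and entries with no shared experiment
are missing outright. On an imputed-complete grid the matrix is
complete, which is what makes `clusterEntities` (agglomerative
clustering on `1 - r`) possible; average linkage is the default for
correlation-derived distances, the linkage is configurable, and
entities are ordered lexicographically beforehand so ties merge
deterministically.

## The synthetic-data generator

`generateGrid` draws a grid whose every map follows a per-cell intensity
surface: a biosample-specific power-law distance kernel
`(1 + d)^(-gamma_b)`; an assay-specific distance tilt
`(1 + d)^(-delta_a)` emulating protocol contact selection (negative
tilts favour long-range contacts, as barcoding-based assays do relative
to ligation-based ones); a compartment term (`1 + beta_b` for same-sign
bin pairs, `1 - beta_b / 2` otherwise) over a blocky ±1 profile; and a
domain term (`tau_b` within an inter-boundary segment). The structural
product is scaled to an expected `depth` of total counts, then
multiplied by a rank-one interaction `exp(s · u_b · v_a)`; placing the
interaction after depth scaling matters, because a per-map scalar
applied before normalization would cancel, whereas applied after it
survives the `log(x + 1)` transform as a genuine shape distortion that
no sum of a row effect and a column effect can reproduce — precisely
the signal that separates the factorization model from the cross-mean
baseline. Counts are Poisson draws per unordered pair, mirrored;
`noise = "none"` returns intensities for analytic tests. Hidden cells
are redrawn until every biosample and assay keeps at least two observed
maps.

What passing tests on this generator do show: the pipeline recovers
planted decay, compartment, and domain structure; training learns
transferable biosample/assay representations; model selection and the
baselines behave as specified. What they do not show: performance on
real contact maps, whose noise is not Poisson at the bin level
(restriction-fragment and mappability bias, ligation artifacts,
cluster-size effects in barcoding assays are all absent), whose
compartment profiles are not clean ±1 blocks, and whose grids are far
sparser and smaller-sample than any simulation chooses to be.

## Pinned analysis conditions and problem sizes

The acceptance analyses run on a pinned configuration
(`generateAcceptanceGrid`): 6 biosamples × 5 assays × 120 bins, Poisson
noise at an expected depth of 2e5 counts per map, decay exponents
0.7–1.4, compartment strengths 0.15–0.5, domain enrichments 1.4–2.4,
assay tilts −0.25–0.25, interaction scale 0.6, and 30% of cells hidden.
Training uses the default architecture with a reduced budget — batches
of 2,000 examples, 100 batches per epoch, up to 15 epochs with early
stopping after 5 epochs without validation improvement — chosen as a
desk-scale budget on which the learning curve has already passed its
validation minimum (the optimizer reaches its best validation epoch
within the first few epochs on this grid and overfits afterwards, which
is exactly the regime validation-based model selection is designed
for). The half-training ablation drops 50% of the training experiments
and retrains under the identical budget.

## Known limitations

* Single-chromosome, cis-only maps; no trans contacts and no joint
  training across chromosomes.
* The distance-embedding table grows linearly with `nBins`; very fine
  resolutions would need log-binned distances, which the literal raw
  indexing deliberately avoids.
* Diagonal predictions are extrapolations (training never samples
  `i == j`).
* Binary `.cool`/`.hic` readers are out of scope; the two text formats
  are the interchange contract.
* The convolutional variant is a forward-pass encoder only.
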