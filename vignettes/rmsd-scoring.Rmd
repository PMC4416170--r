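---
title: "RMSD-response scoring functions for docking pose identification"
author: "poseforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RMSD-response scoring functions for docking pose identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseforge)
```

## The problem

Molecular docking programs generate many candidate binding poses for a
ligand in a receptor's binding site; a scoring function (SF) must then
decide which pose is closest to the native, experimentally observed
binding mode. The classical approach scores poses by *predicted binding
affinity* (BA) and ranks them in descending order, on the implicit
assumption that a higher predicted affinity means a lower deviation from
the native pose. poseforge implements the alternative this package is
built around: train regression models with the pose's *RMSD to the
native structure* as the response and rank poses in ascending order of
predicted RMSD.

The RMSD response has two structural advantages over BA. First, the
model predicts the very quantity used to judge poses. Second,
affinities are experimental measurements that exist only for the native
complex — one training record per complex — whereas RMSD is computable
for every generated pose, so an RMSD-response training table scales as
(number of complexes) x (poses per complex). The package's evaluation
harnesses quantify both effects.

## Pose geometry and descriptors

All structures are heavy-atom only: hydrogens are dropped on input, and
decoy RMSDs in this literature are heavy-atom quantities. RMSD between
two poses is computed over index-paired atoms in the shared receptor
frame, **without** superposition (`poseRmsd()`): docking decoys live in
the receptor's coordinate system, so a rigid displacement is a real
scoring error, not an alignment artefact. No automorphism (symmetry)
correction is applied; `atomMapping` exposes a hook for plugging in an
external atom-matching strategy. Whether published decoy RMSDs used
symmetry correction is not documented; we flag this rather than guess.

The geometrical descriptor family R counts protein-ligand element pairs
over \{C, N, O, S\} x \{C, N, O, F, P, S, Cl, Br, I\}: 36 counts of
pairs within 12 Angstrom (`pairCounts()`), with the distance test
`0 < d <= cutoff` — "within" is read as inclusive, and the boundary case
is pinned by tests. The binned variant (`binnedPairCounts()`) resolves
each count over five 4 Angstrom intervals (0,4], (4,8], ..., (16,20],
giving 36 x 5 = 180 features. Atoms of other elements are retained in
structures but ignored by featurization, keeping the 36-key schema
fixed. The three remaining families — X (6 empirical scoring terms),
A (30 physicochemical terms), G (14 docking-tool descriptors) — are
ingested as externally computed tables (`loadExternalFeatures()`);
computing them is out of scope. Note the arithmetic of the extended
pool: 6 + 30 + 14 + 180 = 230 columns, although the benchmark
literature's headline count for this pool is 220; the package exposes
the widths and lets the experiment configuration choose, resolving
nothing silently. Feature-curve defaults (sizes 20, 60, ..., 220)
follow the published grid.

## Decoy-set construction

`buildDecoySet()` reproduces the benchmark recipe: candidate poses more
than 10 Angstrom from the native pose are discarded, survivors fall
into ten 1 Angstrom bins ((k-1, k] per bin k; an exact-native pose at
RMSD 0 is outside every half-open bin and enters bin 1 only under
`includeNative`), each bin is clustered and the lowest-energy member of
each cluster is kept, ties to the lowest pose index. Ten bins x ten
clusters give up to 100 representatives (`decoyPreset("test100")`); the
lighter training regime keeps five per bin (`"train50"`).
Under-populated bins simply contribute fewer representatives, which is
also the behaviour of the published sets.

Two choices here were genuinely open. The clustering "by similarity" is
implemented as complete-linkage hierarchical clustering on the pairwise
pose-pose heavy-atom RMSD matrix — the most defensible reading, and
deterministic given input order; the function is pluggable if another
similarity is preferred. The per-pose energy used for representative
selection defaults to a user-provided column (docking tools supply
these in practice); a documented Lennard-Jones-like surrogate
(`builtinEnergy()`, `4((r0/d)^12 - (r0/d)^6)`, r0 = 3.5 Angstrom,
pairs within 8 Angstrom, distances clamped at 1 Angstrom) exists solely
so the pipeline runs on synthetic data. It has no physical calibration.

## The six scoring functions

`fitScoringModel()` trains MLR, MARS, kNN, SVM, RF or BRT with either
response. Parameters that the benchmark fixes are fixed here: 2000
trees for RF, shrinkage 0.005 for BRT. Tuned values for all 15 feature
combinations ship in `extdata/tuned_params.csv` (`tunedParams()`).
`tuneScoringModel()` re-derives parameters by grid search minimising
MSE under 10-fold cross-validation (MARS, kNN, SVM, BRT) or out-of-bag
error (RF `mtry`), deterministic in the seed, ties to the first grid
point.

Backend choices, in decreasing order of "buy":

* **MLR** is `stats::lm`; **SVM** is `e1071::svm` with an RBF kernel —
  the width parameter sigma follows the kernel
  `exp(-||u-v||^2 / (2 sigma^2))`, so `gamma = 1/(2 sigma^2)`; the
  mapping is explicit because libraries parameterise by gamma.
  **RF** is `randomForest`.
* **BRT** rides on `xgboost` (gradient-boosted regression trees:
  `eta` = shrinkage, `max_depth` = interaction depth); the tree count,
  when not given, is selected by internal 5-fold cross-validation with
  early stopping, mirroring the self-tuning tree count of classical
  gradient boosting machines.
* **MARS** and **kNN** are authored in-house. The MARS implementation
  is a standard Friedman-style forward pass over reflected hinge pairs
  (candidate knots at up to 20 quantiles per predictor, interactions up
  to `degree`) followed by backward pruning under
  `GCV = RSS/n / (1 - C(M)/n)^2` with `C(M) = M + penalty (M-1)/2`;
  the number of terms is therefore auto-selected, and only `degree` and
  `penalty` are tuned, as in the benchmark protocol. kNN regression
  uses the Minkowski distance of degree `q` (the tuned value is q = 1,
  i.e. Manhattan).

Features are standardised to zero mean and unit variance for kNN and
SVM only — both are distance/kernel methods whose answers depend on
scale; linear and tree methods see raw features. Whether the original
protocol standardised is unstated; this is our documented choice. BA
responses are used as given (the convention is a negative log of the
dissociation/inhibition constant); no transformation is applied.
`rankPoses()` sorts ascending for RMSD models and descending for BA
models, with ties broken by original pose order so optimistic or
pessimistic re-analyses remain possible.

## Docking-power evaluation

The success statistic `S_C^N` is the percentage of complexes for which
at least one of the N top-ranked poses lies within C Angstrom of the
native pose (`successRate()`). The hit test is inclusive (`<= C`), and
C = 0 — "the best-scoring pose *is* the native" — is implemented as
RMSD below a 1e-6 Angstrom tolerance to be robust to floating-point
noise. Every report (`evaluateModel()`) carries the full cutoff x depth
grid (defaults C in \{0,1,2,3\}, N in \{1,2,3,5\}) plus per-complex hit
indicators, and the class validity asserts monotonicity of the rates in
both C and N. `includeNative = FALSE` removes exact-native rows before
ranking to measure the cost of the native pose being absent from the
candidate pool.

`learningCurve()` retrains on random subsets — a fraction of complexes,
or a fixed number of poses per complex (the native row is retained so
BA responses stay defined) — and `featureCurve()` on random feature
subsets drawn without replacement, each averaged over repeated draws
with seeds derived deterministically from the master seed.

## Novel-target splits

`constrainedSplit()` reproduces the novel-target protocol: draw a test
set of `nTest` complexes at random; accept a training set of `nTrain`
complexes only from those whose precomputed binding-site similarity to
*every* test complex is at most the cutoff S; redraw the test set when
too few qualify, and report the best achievable training size on
exhaustion. Similarities arrive as a validated symmetric percentage
matrix; which residues define the binding site, and the aligner that
produced the numbers, are deliberately hidden behind that abstraction.
`sequenceIdentity()` (global alignment, match +1 / mismatch 0 / gap -1,
identity = matches / alignment length) is a deterministic built-in
surrogate for building test matrices — it is not claimed to reproduce
BLAST similarities.

## The synthetic benchmark

`makeBenchmark()` makes the whole pipeline runnable without downloads.
Each complex is a random receptor shell (heavy atoms at radii 6-12
Angstrom around the pocket centre) plus a native ligand in a 3 Angstrom
pocket sphere; candidate poses are produced by `perturbToRmsd()`, which
rescales a random rigid-plus-jitter displacement field so the achieved
RMSD equals the target *exactly* (to 1e-6) — exactness is preferred
over physical realism. Pose RMSD targets are uniform on (0, 12]
Angstrom, the spread of a pooled multi-program docking run before the
10 Angstrom filter.

The feature table couples real geometry (R features computed from the
generated structures) with 50 synthetic X/A/G-like columns, of which 25
(by default) are linear in the pose's true RMSD with unit Gaussian
noise and the rest are pure noise; X-like columns also carry a
ligand-size component. The affinity label, `BA = 10 - 0.2 x
(ligand heavy atoms) + noise`, exists on native rows only. This
reproduces the mechanism under study: BA-mode tables are small and
their response is only indirectly related to pose quality, while
RMSD-mode tables are large and aligned with the ranking task. That is
exactly what the harnesses exercise, and it is also the limit of what
passing tests show — synthetic descriptors are *statistically* linked
to RMSD by construction, so absolute success rates here say nothing
about real protein-ligand data; only directions and mechanisms
(RMSD-mode > BA-mode; more data helps) transfer.

Default scenario sizes are the package's study conditions: 200
complexes x 20 poses for the head-to-head response comparison (fitted
with the shipped tuned parameters for the XARG signature), a 100-complex
independent test scenario, and reduced sizes for the curve harnesses
(80 training complexes at 20 poses, 60 test complexes at 10 poses, 10
repeats, RF with 300 trees for the curve fits, training fractions 10,
55 and 100 percent and pose counts 2 and 20) — chosen so the full suite
stays desk-scale while the compared quantities keep comfortable
margins.

## Numerical and degenerate-input policy

* Ties: representative selection, ranking and tuning all break ties to
  the lowest index / first grid point, documented per function.
* Missing values in external descriptor tables are hard errors — no
  imputation, since silent imputation corrupts benchmarks.
* Empty bins, under-populated bins and fewer poses than clusters
  degrade gracefully (fewer clusters/representatives, never an error);
  empty rankings and non-finite features are errors that name the
  offending complex or rows.
* All randomness flows through explicit integer seeds (default
  20070101); child seeds are derived, never reused, and generators
  restore the caller's RNG state.

## Known limitations

The X/A/G descriptor families are ingested, never computed; symmetry-
corrected RMSD is not implemented (hook only); mmCIF and protonation
are out of scope; the built-in similarity surrogate is not BLAST; and
published benchmark success rates are not reproducible here because
they require the original structure sets, decoy sets and proprietary
descriptor tools.
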