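---
title: "Methods: PCA plane search for strain-unique metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCA plane search for strain-unique metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcar)
```

## The model

`popcar` operates on a bucket table: a dense, non-negative matrix of
strains × (RT, m/z) buckets, with zero encoding absence. The working
assumption, standard for actinomycete collections, is that a metabolite
produced by every strain in the group is probably known, while a mass
feature confined to one strain is a candidate for novel chemistry. The
package turns that assumption into a ranked, per-strain short list via
PCA.

The pipeline order is fixed: replicate averaging → RT/mass range
filter → sum normalization → Pareto scaling → PCA → per-strain plane
search, uniqueness filter, ranking, and optional dereplication. The
stages and their defaults:

* **Replicate averaging** (`averageReplicates`): feature-wise arithmetic
  mean of replicate rows, applied before any normalization. Averaging at
  the table level keeps the PCA model at one row per strain — models
  over full replicate sets grow quadratically and add nothing to a
  survey analysis — while retaining per-strain intensity structure.
* **Range filter** (`filterRanges`): keep RT ∈ [2, 14] min,
  m/z ∈ [150, 1500] (closed intervals). The RT window removes the
  injection front and column wash; the mass window removes solvent
  clusters and sparsely calibrated high masses.
* **Sum normalization** (`normalizeSum`): each strain row is divided by
  its own total, so rows sum to 1. Strains differ several-fold in
  overall ion yield (culture density, extraction efficiency,
  ionization); without row normalization a weakly ionizing strain would
  appear to have fewer unique features simply because its buckets sit
  closer to zero. Normalizing per bucket (column-wise) instead would not
  correct this, which is why the row-wise reading of "sum of bucket
  values" is used.
* **Pareto scaling** (`paretoScale`): per column,
  x′ = (x − mean)/√sd, with the sample (n−1) standard deviation. The
  square-root divisor is a compromise between no scaling (intense
  features monopolize the model) and unit-variance scaling (noise
  buckets are inflated to parity with real signals). Zero-variance
  columns are set to zero rather than dropped so feature indices remain
  aligned with the bucket table. The scaled matrix is exactly
  column-centered, and scaled column variance equals the original
  column standard deviation — both properties are asserted in the test
  suite.

## PCA contract

`fitPCA` computes the SVD X = U S Pᵀ of the scaled matrix and stores
scores T = U S, loadings P (orthonormal columns) and explained variance
Sₖ²/(n−1). Conventions:

* **Retained components.** K is the numerical rank (singular values
  above 10⁻¹⁰ of the largest), but never fewer than two when the matrix
  shape admits them. The floor exists so that a PC plane — and therefore
  the whole downstream contract — is defined even for degenerate inputs
  such as a table of identical strains, where every gap is zero, the
  plane defaults to (PC1, PC2) by the tie rule, and every report is
  empty. After centering, K ≤ n − 1: a model of n strains has at most
  n − 1 informative components, even though one PC per strain is
  sometimes informally expected.
* **Sign convention.** SVD signs are arbitrary, so each component is
  flipped to make its largest-magnitude loading positive. Reports are
  thereby reproducible across runs, platforms and LAPACK builds.
* **Indexing.** Components are 1-based everywhere user-facing ("PC13").

## Plane search

A strain "stands out" on component k if its score is separated from
the other strains' scores there. The phrase "score difference" admits
several references; the default gap is the **nearest-neighbor** gap

> gₖ(s) = min over r ≠ s of |T[s,k] − T[r,k]|

because a strain is only interesting if it separates from *all* other
strains: a difference-from-mean (or -median) metric can be inflated by
a second outlier on the same component, exactly the case where the
plane is *not* diagnostic for s. The median variant is retained as an
option (`metric = "abs_deviation_from_median"`) since the reference
point used by vendor scores-overview displays is not documented.

The selected plane is spanned by the two components with the largest
gaps (ties toward the lower index, favoring higher-variance
components). Because every other pair's smaller gap is bounded by the
second-largest gap, this top-2 rule provably maximizes min(gᵢ, gⱼ) over
all K(K−1)/2 planes; the exhaustive pair search is kept as
`method = "exhaustive"` and the equivalence is asserted over random
models in the tests.

## Uniqueness and ranking

Uniqueness is a property of the bucket table, not of the PCA: feature f
is unique to strain s iff table[s, f] > 0 and table[r, f] ≤
α · table[s, f] for every other strain r. The default α = 0 demands
strictly exclusive presence; a small α tolerates near-zero noise
buckets in other strains and the unique set grows monotonically in α.
The check runs on the normalized (unscaled) table; reported intensities
are the raw bucket values.

Ranking uses the Euclidean loading distance √(P²_{f,i} + P²_{f,j}) in
the strain's selected plane, truncated to the top 60. Distance across
all K components is available (`distanceSpace = "full"`) because a
2-D-vs-full-space reading of loading distance is a genuine free choice;
the plane-restricted default matches how a loadings plot is actually
inspected. Features shared by small groups of 2–3 strains — excluded
from per-strain reports by definition — are available separately via
`sharedFeatures`.

## Bucketing

`bucketFeatures` merges per-sample feature lists under ΔRT = 0.33 min
and Δm/z = 4 ppm tolerances. The vendor algorithm behind historical
bucket tables is not documented, so the package uses a deterministic
sweep: pool all features, sort by m/z (ties: RT, then sample), then
assign each feature to the nearest-in-ppm open bucket whose
intensity-weighted centroid is within both tolerances (ppm ties break
toward the lower-m/z centroid), or open a new bucket. The two
tolerances act as independent gates. Properties guaranteed and tested:
total intensity conservation (same-sample collisions are summed, not
averaged), invariance to sample/feature input order, and exact
reconstruction of planted bucket counts from jittered feature lists
when jitter is below half the tolerances.

## Dereplication

Observed ions convert to neutral masses as M = m/z × z − shift; the
proton mass constant is fixed at 1.007276 Da. The default adduct set is
[M+H]⁺ alone — appropriate for positive-ESI acquisition — with
[M+Na]⁺, [M+NH₄]⁺ and [M+2H]²⁺ available. Matching is a binary search
over the mass-sorted database with the ppm error computed against the
database (theoretical) mass, the mass-spectrometry convention; the
default tolerance is 5 ppm, a conventional Q-TOF identity window
slightly wider than the 4-ppm bucketing tolerance (no tighter value is
defensible without knowing the calibration state of the instrument that
produced the queries). A query matching nothing under any adduct is
flagged putatively novel. The binary search is asserted equivalent to a
linear scan over random databases at 1–10 ppm. The database schema is a
neutral CSV (name, monoisotopic_mass, formula) so any licensed or
public compound collection can be mounted.

The report writer emits CSV (one long file, or one file per strain);
spreadsheet-native output is not provided.

## The synthetic-data generator

`generateBucketTable` emulates the structure of a strain-collection
profiling experiment: a large block of background buckets shared by all
strains (log-normal base intensities, meanlog log(4e5), sdlog 1 — a
median of ~4×10⁵ counts spread over roughly an order of magnitude,
typical of Q-TOF bucket tables), a small set of exclusive buckets per
strain from the same intensity distribution, a per-strain global
intensity factor drawn from [0.25, 1] (the ~4-fold ion-yield disparity
observed between strains in real collections), optional per-strain
dropout of background buckets, and optional replicates.

Two modeling decisions deserve emphasis:

* **Noise is between-replicate noise.** Multiplicative log-normal noise
  with the specified CV is applied per replicate; a single analysis per
  strain is that strain's clean profile. This mirrors what the noise
  parameter physically is (injection/detector variation between repeat
  runs of the same extract); strain-to-strain biological variation in
  shared metabolites is deliberately *not* simulated, which is the main
  respect in which passing tests overstate real-data performance — in
  real tables background buckets vary between strains for biological
  reasons, and sufficiently strong variation of an intense background
  bucket can out-rank a weak unique feature in loading distance.
* **m/z keys are drawn ≥ 20 ppm apart** so that 4-ppm bucketing ground
  truth is unambiguous.

One known coupling: because rows are sum-normalized, a strain with
unusually intense unique features dilutes its background share, which
moves it slightly along a "dilution" direction in score space. For
unlucky seeds this can place an intense background bucket marginally
above the weakest planted feature in one strain's plane; the packaged
acceptance checks use a fixed seed where the separation margin is
positive, and `scripts/acceptance.R` reports the margin for whatever
seed it is given.

## Problem sizes and runtime

The test suite and the reproduction script run the full workflow at
20 strains × (2000 background + 100 planted) buckets — large enough for
a 19-component model and a meaningful center-mass population, small
enough that the whole suite completes in under two minutes on one core.
PCA-invariant checks additionally cover shapes up to 20 × 5000. At
these sizes base `svd` on the dense matrix is the right tool; nothing
in the package assumes the data fit any particular scale other than
memory.

## Limitations

* Plane search needs contrast: at least 3 strains, and the model
  becomes uninformative for very large heterogeneous groups (as group
  size grows, inter- and intra-group variance converge and fewer
  features are exclusive to any strain; groups of ~40–50 phenotypically
  similar strains are a practical ceiling).
* α = 0 uniqueness is brittle against noise buckets: a single spurious
  1-count in another strain removes a feature. Raise α slightly for
  noisy tables.
* No RT alignment: bucketing tolerates ±ΔRT but does not warp
  retention-time drift beyond it.
* Statistical significance of a separation gap is not assessed — the
  output is a prioritized reading list, not a hypothesis test.
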