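---
title: "Models and methods in nichemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nichemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemap)
```

`nichemap` analyzes imaging-based single-cell spatial transcriptomics of
bone marrow around a designated leukemia population. This vignette is
the package's account of its models and the choices behind them: what
each statistic assumes, which knobs matter, what the synthetic tissue
generator does and does not emulate, and the numerical decisions that a
reimplementer would otherwise have to guess.

## Coordinates, polygons, and distances

Every cell is a simple polygon in FOV-local micrometers, origin at the
lower-left corner, y increasing upward. Label rasters use one scalar
`pixel_size` (default 0.18 µm/px) to convert; a pixel belongs to an
object when its center falls inside the polygon. Polygons are stored as
open rings; a repeated closing vertex is dropped on input.

All cell-to-cell distances are **edge-to-edge**: the minimum Euclidean
distance between the two boundary polylines. Touching, crossing, and
containment all give 0 — overlapping segmentations must never produce
negative or undefined separations. Centroid distances overstate
separation for large or irregular cells, which is exactly the regime
where niche composition matters, so the edge convention is load-bearing,
not cosmetic. `build_distance_table()` prunes candidate pairs with
bounding-box gaps before computing exact segment-pair distances; the
result is defined to equal the all-pairs brute force, and the test suite
asserts that equality against an independently written scalar oracle on
randomized FOVs.

Ring neighborhoods around each leukemia cell use half-open,
lower-inclusive bands `[0,5), [5,15), [15,25), [25,35), [35,45)` µm. The
band description "0 to 5, 5 to 15" does not by itself fix what happens
at the shared endpoints; lower-inclusive half-open intervals make
touching cells (distance 0) fall in the innermost band and leave every
distance in exactly one band. Cells at or beyond the outermost edge are
omitted. A neighbor may sit in rings of several leukemia cells;
overlapping neighborhoods are deliberately left uncorrected, because the
ring model downstream is defined on exactly these possibly-overlapping
counts.

## The synthetic tissue generator

The generator exists so that every downstream stage can be tested
against known ground truth. Defaults are the conditions the package is
designed around: FOVs of 985 × 657 µm, a 960-gene panel plus 19
negative-control probes, a 10% leukemia fraction, and a log-normal
per-cell size factor (µ = 0, σ = 0.35) scaled so the median per-cell
depth is near 100 transcripts — the sparse regime of imaging-based
panels.

Cells are seeded by a minimum-separation point process (rejection
sampling at 0.55·√(area/n) separation), and their boundaries are the
Voronoi tessellation of the seeds clipped to the FOV, with each convex
cell offset inward by half the `polygon_gap` (default 1 µm) so polygons
are strictly disjoint. Voronoi polygons rather than circles make the
edge-vs-centroid distinction material. Leukemia seeds are placed first;
each remaining seed draws its type from the base proportions, reweighted
by an enrichment multiplier when the seed lies within
`enrichment_radius` of a leukemia seed. Enrichment acts at placement
time (thinning), not by relabeling afterwards, so the ring model's rate
ratio has a known generative analogue.

Counts are independent Poisson draws, gene by cell, at
`size_factor × profile_rate`; negative-control probes are flat Poisson
background (rate 0.02) with no size factor. Cells of the receiver type
within `lr_effect$radius` of a leukemia cell (true edge distance) have
the receptor gene's rate multiplied by `lr_effect$fold` — default fold 3
within 5 µm, mirroring a proximity-induced signaling effect. Red blood
cells are anucleate and get near-zero rates. Transcript positions are
uniform within each cell's polygon, so column sums of the count matrix
equal per-cell transcript counts by construction.

What the generator does **not** emulate: real marrow histology,
segmentation noise beyond membrane dropout, spatial autocorrelation of
expression within cell types, probe-specific efficiency, or 3-D
structure. Passing tests on this generator show the chain is correct
and calibrated under its own assumptions; they do not certify
performance on tissue whose violations of those assumptions are
material.

## Mask fusion and segmentation scoring

A nucleus pairs with the membrane object containing the largest fraction
of its pixels, if that fraction reaches `pair_overlap_min` (default
0.5); ties break by larger absolute overlap, then smaller membrane
label. A membrane claimed by several nuclei keeps the nucleus of largest
overlap; losers fall back to expansion. Unpaired nuclei are dilated
isotropically by `expansion_radius` (default 3 µm), never overwriting
existing fused objects; where two expansions collide, the pixel goes to
the nearer nucleus, ties to the smaller label. The expansion bound
prevents the failure mode that motivates membrane staining in the first
place — nuclei expanded so far they capture neighboring cells'
transcripts.

Segmentation scoring matches predicted to truth objects greedily in
descending IOU order, one-to-one, counting pairs with IOU ≥ 0.7 as true
positives, and reports `F1 = TP / (TP + (FP + FN)/2)`. Greedy matching
(rather than optimal assignment) is standard for instance-segmentation
F1 and deterministic; the choice is documented because the score depends
on it. F1 is non-increasing in the IOU threshold and symmetric under
swapping prediction and truth (FP and FN exchange).

## The ring-composition model

For each leukemia cell and ring, `build_ring_counts()` emits one record
per focal type: the focal-type count and the ring's total typed-neighbor
count. RBCs are excluded (anucleate, no usable transcriptome); all other
typed cells, including other leukemia cells, count toward totals — the
inclusion is configurable via `exclude_types`.

Per focal type, the model is a Poisson GLMM:

`log E[count] = log(total) + response × timepoint × ring + u_FOV`,

with `u_FOV ~ N(0, σ²)` and the full three-way factorial of fixed
effects. The offset converts counts to ring-level proportions; the FOV
random intercept carries within-FOV correlation. Estimation is
delegated to `lme4::glmer`. The default is `nAGQ = 0` (PIRLS-profiled
fit): one model is fit per cell type and the package's own calibration
studies fit hundreds, and at the cohort scales used here the Wald test
at `nAGQ = 0` holds its nominal level — the acceptance run measures the
type-I error over 500 null cohorts and the suite requires it to sit in
[0.03, 0.07] at nominal 0.05. `nAGQ = 1` (Laplace) is a parameter away
for final reporting.

Contrasts are linear combinations of fixed effects built from
model-matrix rows, per ring: responders post-ICI vs baseline,
nonresponders post-ICI vs baseline, and responders vs nonresponders at
baseline. Wald p-values are Bonferroni-adjusted over the whole family —
all contrasts of all cell-type models passed in — the only family the
method's definition names. A plain Poisson GLM fallback (same fixed
effects, no FOV term) exists as a cross-check; per-FOV fixed effects
are not usable for this purpose because response and timepoint are
constant within an FOV and would be aliased.

`simulate_ring_cohort()` generates model-level cohorts for recovery and
calibration studies: 6 patients (half responders), 10 FOVs per patient
per timepoint, 3 leukemia cells per FOV, 5 rings, FOV random intercepts
with SD 0.3, ring totals Poisson(30)+1, and a uniform post-vs-baseline
rate ratio for responders. At this scale the 95% Wald CI covers a true
rate ratio of 2.5 in at least 90 of 100 replicates (the acceptance run
reports the observed coverage and mean estimate).

## The density-shift statistic

For target type T and time point A, the sample is the multiset of
minimum edge distances from each T cell to the leukemia population,
pooled over the sample's FOVs (FOVs without leukemia cells are skipped
with a warning). Densities are Gaussian KDEs with Silverman's
rule-of-thumb bandwidth — the default family of R's `density()` — with
two numerical choices the estimator needs on this support:

* **Reflection at zero.** Distances are non-negative and often pile up
  near contact; an unbounded KDE leaks mass below zero and can lose
  >10% of its integral. Reflecting the data about 0 restores
  integration to 1 (the suite checks 1 ± 2% by trapezoid rule).
* **A bandwidth floor at the grid resolution.** A sample of cells all
  at the exact contact distance has zero variance; Silverman's rule
  collapses and the density spike would fall between grid points.
  Flooring the bandwidth at the median grid spacing keeps such samples
  representable.

The shift curve is `S(x) = pdf_A(x) − pdf_B(x)` on a 512-point grid
over [0, 45] µm (both configurable). The background repeats the
construction on 100 permutations: per time point, N cells drawn without
replacement from the K non-leukemia, non-RBC cells of each FOV, with
permutation j's shift pairing the j-th draw of each time point — the
literal reading of the background shift's definition; unpaired
backgrounds would inflate the background SD slightly. A grid point is
flagged when the observed shift lies strictly outside one standard
deviation of the permutation shifts, in either direction. This ±1 SD
criterion is deliberately liberal (roughly a 32% pointwise rate under
the null, before smoothing-induced correlation); the package
characterizes it rather than "fixing" it: under random relabeling the
observed curve's exceedance rate matches the background's own
leave-one-out exceedance rate. For display, the curve is divided by the
per-point background median, its absolute value floored at machine
epsilon.

`density_shift_validation()` rebuilds the method's positive control:
assign the target label to the N cells closest to (or furthest from)
the leukemia population at one time point and to N random cells at the
other. The closest-cell variant must flag a positive shift below 10 µm,
the furthest-cell variant a positive shift beyond 30 µm (equivalently a
deficit near zero). At the default validation scale (150 cells in a
300 × 200 µm FOV, N = 25, J = 100) detection is near-certain; the
acceptance run reports the observed detection rate over 100 seeded
replicates per variant and the suite requires at least 95.

## Proximity-conditioned ligand-receptor testing

Non-leukemia cells are grouped by distance to the nearest leukemia
cell: close (≤ 5 µm), far (≥ 30 µm), excluded in between. The gap
between cutoffs is intentional — it keeps the groups biologically
distinct under segmentation jitter.

Screening: for each candidate gene on the leukemia side of the pair
table, compute per-FOV, per-type pseudo-bulk means (raw counts averaged
over the type's cells in the FOV), then each type's median across FOVs.
A gene is leukemia-high when leukemia's median exceeds the mean of the
other types' medians by more than two of their standard deviations. The
dispersion is computed over the non-leukemia types' medians — the
natural reading when the comparison set is "the expression of other
cell types" — and is configurable.

Testing: for each leukemia-high gene, each complementary partner gene,
each non-leukemia type, and each sample, the per-FOV mean partner
expression among close cells is compared with far cells by a two-sided
Mann-Whitney U test across FOV replicates (a FOV is usable when both
groups are non-empty; below 3 usable FOVs the row reports a reason
instead of a p-value). Pseudo-bulk means of raw counts — not per-cell
normalized values — are compared, matching the mean-aggregation
convention; a median-aggregation flag would be a one-line change in
`.fov_type_means`. Benjamini-Hochberg adjustment is applied within each
(orientation, sample) family and the method is recorded in the result's
metadata; Bonferroni is reserved for the ring model where that family
is explicit.

Two properties worth knowing when reading results: the exact rank-sum
p-value is discrete, so with few FOV replicates its attainable values
are coarse (with 3 usable FOVs the smallest two-sided p is 0.1), and
the close group of a rare type can be empty in many FOVs. Power
studies should therefore use enough FOVs that the injected effect can
express itself: the acceptance run uses 12-FOV cohorts of 160 cells in
400 × 280 µm FOVs (leukemia spacing ~40 µm, so both close and far
groups are populated) for power, and 20-FOV cohorts for null
calibration, where the finer p-value lattice makes the
Kolmogorov-Smirnov uniformity check meaningful.

## Reference-based cell typing

QC first: cells with fewer than 20 transcripts are removed, then FOVs
with fewer than 300 remaining cells. Reference cells are those with
exactly one positive marker type, where "positive" means the mean
marker count exceeds a threshold (default 0 — any marker evidence; the
threshold is configurable because no canonical value exists). Reference
profiles are per-type means of all panel genes over the type's
reference cells.

Assignment models each cell's counts as independent Poisson with rate
`total × (profile + b) / Σ(profile + b)`, where `b` is the mean
negative-control count over all probes and cells — an additive flat
background, the simplest defensible form of probe-background
adjustment, applied identically to every gene and type. Under a uniform
prior, the posterior over types depends on the data only through
`Σ_g y_g log p_g,t`, so assignment is invariant to multiplying all
profiles by a constant, and posteriors sum to one by construction. A
second round re-scores cells in designated broad classes (lymphocytes)
against subtype profiles only; it can change the subtype, never the
broad class. Size validation reports the fraction of cells above an
area threshold (default 648 µm², i.e. 20,000 px at 0.18 µm/px) that
carry the expected label — the megakaryocyte check.

At the generator's default profiles, typing accuracy at median depth
~100 is well above 80% and is non-decreasing in depth (checked at
median depths 50, 100, 500); both facts are asserted by the suite with
fixed seeds, and the acceptance run reports the observed accuracies.

## Simulation scales and runtime

The acceptance checks run on one CPU in roughly a quarter hour. Scales
were chosen once, as the smallest sizes at which each property is
expressed cleanly: 100 random 50-cell FOVs for geometry equivalence;
100 recovery and 500 null cohorts for the ring model; 100 seeded
replicates per density-shift variant; 100 power and ~7 null cohorts
(≥500 pair-tests) for ligand-receptor; 420 cells per depth for typing.
The generator's tissue defaults (FOV size, panel size, depth, leukemia
fraction) stay at the study conditions; only counts of replicates,
cells per test FOV, and FOVs per cohort vary between checks.

## Known limitations

* Geometry is 2-D; z-structure is assumed collapsed upstream.
* The ring model ignores overlap between neighborhoods of nearby
  leukemia cells, by design.
* The density-shift criterion is intentionally liberal (±1 SD) and is
  characterized, not corrected; no multiplicity control is applied
  across type pairs.
* The exact Mann-Whitney p-values are discrete; calibration statements
  assume enough FOV replicates for the lattice to be fine.
* The typing model assumes gene independence given type and a flat
  background; structured background (cell-to-cell contamination) is out
  of scope.
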