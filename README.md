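# nichemap

Spatial neighborhood analysis of single-cell spatial transcriptomics
around a leukemia population in bone marrow.

Imaging-based spatial transcriptomics (CosMx-style: ~1 mm² fields of
view, a ~10³-gene panel, a median of ~10² transcripts per cell) captures
both where each cell sits and what it expresses. `nichemap` implements
the analysis chain needed to ask how the composition and signaling of
the niche immediately around leukemia cells changes across treatment
time points and patient response groups:

* **Segmentation-mask fusion and benchmarking** — merge nucleus and
  membrane label images into one mask per cell (nuclei without a
  membrane partner are isotropically expanded, collisions split by
  distance), assign transcripts to fused cells, and score any
  segmentation against ground truth with greedy IOU matching and
  `F1 = TP / (TP + (FP + FN)/2)` at an IOU threshold of 0.7.
* **Edge-to-edge geometry** — cells are polygons; all distances are
  minimum boundary-to-boundary Euclidean distances (touching or
  overlapping cells are at distance 0), with ring neighborhoods
  `[0,5), [5,15), [15,25), [25,35), [35,45)` µm around each leukemia
  cell boundary.
* **Ring-composition model** — per leukemia cell, per ring, per cell
  type counts, modeled as
  `log E[count] = log(total) + response × timepoint × ring` Poisson
  GLMM with a per-FOV random intercept (lme4), rate-ratio contrasts
  (post-ICI vs baseline within response groups; responders vs
  nonresponders at baseline), Bonferroni-adjusted Wald p-values.
* **Density-shift statistic** — per patient, the kernel density of
  minimum distances from a target cell type to the leukemia population
  is compared between two time points: `S(x) = pdf_A(x) − pdf_B(x)`,
  flagged where it falls outside ±1 SD of 100 index-paired permutation
  background shifts, normalized by the per-point background median.
* **Proximity ligand-receptor testing** — non-leukemia cells are split
  into close (≤5 µm) and far (≥30 µm) groups by distance to the nearest
  leukemia cell; leukemia-high genes are screened by a 2-SD rule on
  per-FOV pseudo-bulk medians; partner-gene expression is compared
  close vs far per cell type with a Mann-Whitney U test across FOV
  replicates (BH-adjusted).
* **Reference-based cell typing** — reference cells with exactly one
  positive marker type, per-type mean profiles, Poisson likelihood with
  a flat negative-control background added to every gene, posterior
  assignment under a uniform prior, a second round for lymphocyte
  subtypes, QC at 20 transcripts/cell and 300 cells/FOV, and cell-size
  validation for megakaryocytes (>648 µm²).
* **A synthetic tissue generator** — Voronoi cell polygons with known
  types, controllable enrichment around leukemia cells, sparse panel
  counts with negative-control probes, a proximity ligand-receptor
  effect, and paired nucleus/membrane/truth label images — so the whole
  chain is testable end to end with known ground truth.

## Worked example

```r
library(nichemap)

# a synthetic FOV with ground truth
sim <- simulate_fov(tissue_params(n_cells = 150L, fov_width = 300,
                                  fov_height = 200, n_genes = 80L,
                                  seed = 5L))
sim$cells
#> cell_table: 150 cells in 1 FOV(s); 150 typed
median(Matrix::colSums(sim$counts))
#> [1] 103

# paired masks, fusion, and benchmarking
mp <- simulate_mask_pair(sim$cells, membrane_dropout = 0.3, seed = 9,
                         pixel_size = 0.5)
fz <- fuse_masks(mp$nucleus, mp$membrane)
evaluate_segmentation(fz$fused, mp$truth, iou_threshold = 0.7)
#> seg_eval: TP=149 FP=1 FN=1  F1=0.9933 (IOU >= 0.70)

# ring neighborhoods around leukemia cells and the niche model
leu <- sim$cells$cell_id[sim$cells$cell_type == "leukemia"]
rings <- assign_rings(sim$cells, leu)
head(build_ring_counts(rings, sim$cells), 3)

# model-level cohort: recover a known post-vs-baseline rate ratio
d <- simulate_ring_cohort(n_patients = 6, n_fovs = 10, rr = 2.5, seed = 79)
ct <- niche_contrasts(fit_niche_model(d, "monocyte"))
subset(ct, contrast == "resp_post_vs_base" & ring == 1,
       select = c(rr, ci_lo, ci_hi, p_adj))
#>        rr    ci_lo    ci_hi       p_adj
#> 1 2.21025 1.831976 2.666631 1.82988e-15
```

The fused-mask F1 of 0.993 says that after dropping 30% of membrane
masks, nuclear expansion recovered nearly every cell above the 0.7 IOU
bar; the ring-1 rate ratio of 2.21 (CI 1.83–2.67) covers the generative
2.5-fold enrichment of monocytes around leukemia cells after treatment
in responders.

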