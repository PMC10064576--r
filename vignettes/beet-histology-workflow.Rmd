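---
title: "Phenotyping beet storage-root tissue from micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping beet storage-root tissue from micrographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetmorph)
```

## The tissue and the measurement problem

Storage roots of *Beta vulgaris* are built from concentric cambium rings:
zones of small-celled vascular tissue (VT) alternating with broad zones of
large, sugar-storing parenchyma (SP). Cell size, cell packing and the amount
of wall material differ between genotypes and correlate with mechanical
tissue properties, so breeders want them measured objectively and at scale.
The raw observation is a stitched brightfield mosaic of a stained transverse
section, oriented with the periderm at the left margin and acquired at a
fixed pixel pitch (1.015228 µm/px at 10× in the reference setup).

Three obstacles make naive segmentation insufficient:

1. cells damaged during sectioning lose part of their wall and appear merged;
2. intercellular spaces — voids between adjacent cells — look exactly like
   cells and cannot be told apart by size or shape alone, because a void in
   the parenchyma may be larger than a genuine vascular cell elsewhere;
3. the tissue is heterogeneous along the radial axis, so any size criterion
   must be applied relative to a cell's local neighborhood, not globally.

`beetmorph` implements a complete workflow around these obstacles. The one
robust biological invariant it exploits is that an intercellular space is
always smaller than the cells immediately surrounding it.

## The processing model

**Binarization.** The grayscale image is smoothed (Gaussian, σ = 2),
thresholded automatically (Otsu; cell interiors are the bright phase), opened
twice with disc brushes of size 18 and 21 px, and hole-filled. Opening
removes bright debris smaller than the brush; because morphological closing
of the complement is extensive, the dark wall network itself is never
deleted. A consequence worth stating plainly: an isolated bright object
narrower than about 19 px cannot survive these brushes. At the default pixel
pitch that is ~19 µm, so isolated small vascular cells persist in the mask
only where fragmented walls merge them into wider complexes — which is also
how they appear in real sections, where wall thickness approaches the pixel
pitch. The watershed step was designed around exactly this regime: it
re-splits merged complexes along the ridges of the interior distance map.
We treat this as a property of the image path and validate the
neighborhood/clustering machinery on ground-truth object tables (below),
where every planted object is observable.

**Segmentation and features.** The Euclidean distance map of the cell
interiors is segmented by the watershed transform (plateau tolerance 1 px,
so single convex cells are not shattered). Each object yields area,
perimeter, boundary-radius statistics (mean/sd/max/min), centroid, moment
ellipse (major axis, eccentricity, orientation). The cell diameter is
`2 · mean radius · µm/px`, stored together with its log10. A single-pixel
object has zero diameter; its log-diameter is stored as the sentinel −99 and
the object is dropped by the small-object threshold.

**Ring detection.** Cells are ordered by distance from the periderm and the
diameter-vs-x series is smoothed by loess (span 0.2, degree 2). Local maxima
of the smoothed profile within a sliding window of 150 consecutive cells are
the parenchyma band centers (peaks); maxima of the negated profile are the
cambium rings (valleys), numbered 1… from the periderm inwards. Between two
detected valleys lies one ring zone; each cell's zone is one plus the number
of valleys strictly left of its centroid.

**Artifact and void removal** iterates four steps until a full pass removes
nothing:

1. *Size threshold.* The histogram of log10 diameter (bin width 0.05) is
   smoothed into a continuous curve; if two clearly separated modes exist,
   the minimum between them is the threshold, capped at 0.8 (≈ 6.3 µm) so
   viable cells are never dropped; otherwise the fallback 0.5 (a 3 µm
   diameter) is used.
2. *Neighborhood outlier fence.* For each object the k = 6 nearest
   neighbors by centroid distance are found; neighbors beyond
   Q2 + 1.5·IQR of the six distances are across a gap and dropped.
   An object whose log-diameter lies below Q1 − 1.5·IQR of its own
   neighborhood (itself plus its gated neighbors) is removed as a probable
   intercellular space.
3. *Per-zone 3-cluster k-means* on the scaled morphological features
   (positions and ring number excluded), relabeled so that 1 = smallest,
   3 = largest cells. Zones with fewer than 10 objects fall back to the
   global solution.
4. *Majority rule.* For a cluster-1 focal object with neighbor cluster
   values summing to SUM (mean MEAN, theoretical maximum MAX = 3 ×
   neighbor count): it is an intercellular space if all neighbors are
   cluster 3, or if SUM ≥ MAX − MEAN.

The kept set shrinks weakly every pass, so termination is guaranteed. Pixel
areas of objects removed by steps 2 and 4 accumulate into the master-table
variable `Intercellcount`; step-1 removals are artifacts and are not counted
as intercellular area.

**Tissue typing.** A final 2-cluster k-means on the survivors, size-ordered
the same way: cluster 1 = VT, cluster 2 = SP. After relabeling,
mean(diameter | VT) < mean(diameter | SP) holds by construction; a tie is
broken by cardinality (the larger group is VT, since vascular cells
dominate numerically).

**Reporting.** Per image: the object table plus pixel accounting (total
pixels, ROI pixels after removing the non-tissue margin and edge-touching
objects, wall pixels = dark pixels inside the ROI, intercellular pixels).
Across images: the master table, per-genotype means ± sd of cell count,
max/mean diameter, ring count and wall fraction, cluster shares by count and
area, a Gaussian kernel density estimate of cell size (bandwidth 1 µm, unit
area), and a genotype dendrogram from pairwise Earth Mover's Distance
scores.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `gaussian_sigma` | 2 | px | pre-threshold smoothing |
| `opening_radius_1/2` | 18 / 21 | px (brush size) | debris removal scale |
| `edge_fraction` | 0.05 | of width | peridermal search strip |
| `edge_opening_radius` | 50 | px (brush size) | non-tissue region scale |
| `um_per_px` | 1.015228 | µm/px | calibration |
| `ring_window_w` | 150 | cells | extremum window |
| `ring_span` | 0.2 | — | loess span |
| `ring_min_relief` | 0.05 | of mean diameter | noise floor for extrema |
| `k_neighbors` | 6 | — | neighborhood size |
| `fallback_log_threshold` / `max_log_threshold` | 0.5 / 0.8 | log10 µm | size threshold bounds |
| `kmeans_nstart` / `kmeans_max_iter` | 25 / 1000 | — | clustering restarts |
| `kde_bandwidth` | 1 | µm | size density kernel |
| `emd_permutations` / `emd_n` | 100 / 40 | — | EMD normalization |

All stochastic steps (k-means restarts, EMD subsampling and permutations)
draw from `random_seed`, so identical inputs and configuration reproduce
byte-identical output tables.

## Numerical choices and tie-breaks

- Brush "sizes" are the side/diameter of the disc structuring element (the
  `makeBrush` convention); even sizes round up to odd.
- Quantiles are type-7 (linear interpolation), the default of the R
  environment the workflow targets. The distance gate uses the literal
  median-based fence Q2 + 1.5·IQR; `neighbor_fence = "upper"` switches to
  the conventional Q3-based fence.
- The size-threshold histogram keeps the 0.05 bin width but detects modes on
  a smoothed version of the bin counts (Gaussian kernel, 2-bin sd): on a
  unimodal sample, raw bin-count wiggles would otherwise fake bimodality. A
  mode must reach 10% of the highest mode's height; the valley must drop
  below 75% of the lower mode, else no threshold point is declared and the
  fallback applies.
- Extremum detection requires a window relief of at least `ring_min_relief`
  (5%) of the mean smoothed diameter, so loess-smoothed sampling noise on an
  unstructured profile is never reported as a ring. Plateau ties resolve to
  the leftmost sample; consecutive same-type extrema collapse to the
  strongest so peaks and valleys strictly alternate.
- 8-connectivity for components; flood-fill hole definition (dark areas not
  connected to the border background); hole filling runs after both opening
  cycles.
- Outlier decisions within one pass are taken on a frozen table state and
  applied together; neighborhoods are recomputed after each removal stage.
- Features are re-scaled before every re-clustering pass.
- The two majority-rule criteria (all-neighbors-3; SUM ≥ MAX − MEAN) are
  checked in that order; a focal object with zero gated neighbors is kept
  for lack of evidence.
- Nearest neighbors come from an exact chunked brute-force search (no
  kd-tree library is required at these object counts).
- The EMD score between two genotypes averages the exact 1-D Earth Mover's
  Distance over the z-scored feature dimensions of their per-image summary
  vectors ({mean, sd, max, min} of every retained master-table variable),
  on bootstrap subsamples of size `emd_n`, and divides by the mean of
  `emd_permutations` label-permuted scores. The cited procedure fixes only
  the score-plus-permutation structure; the averaging and normalization
  details here are this package's documented choice, as is average linkage
  for the dendrogram.
- The body-text reading that valleys of the diameter profile are the cambium
  rings is followed; the alternative caption labeling (rings as peaks) is
  treated as a labeling slip, since rings are small-celled by definition.
- The profile fed to loess is the per-cell scatter, not a binned histogram.

## What the synthetic generator emulates

`synthetic_spec()` / `generate_tissue()` build a ring-structured mosaic with
full ground truth: a near-hexagonal centroidal tessellation whose target
cell diameter follows a raised-cosine band profile along x (default five
bands, small cells 12 µm, large cells 35 µm), dark walls (2 px), bright
interiors, intercellular voids stamped at junctions between deep-parenchyma
cells (5% of hosts; 8–14 µm, always smaller than every adjacent cell),
sub-cellular bright specks, an irregular bright non-tissue region at the
left margin, and cells truncated by the borders. Image size defaults to
2000 × 400 px — a scaled-down mosaic with the same ring spacing regime as
the reference setup (about one band per 330 px, ~1100 objects per image).

Cell-diameter dispersion is realized as a smooth coherence field varying
along y (75% of the class sd) plus bounded uniform jitter (66% of the class
sd): neighborhoods in real tissue are developmentally coherent, and the
method's central invariant — a void is smaller than *all* of its neighbors —
presumes locally bounded size variation. The field varies along y only, so
the x diameter profile carries nothing but the planted band structure.

What it does **not** emulate: staining color and its variability, uneven
illumination, stitching seams, genuinely torn tissue, partial-depth cells
from the section thickness, and wall-thickness variation. Passing the
synthetic recovery tests therefore demonstrates the algorithmic machinery
under controlled conditions, not performance on any particular real
micrograph.

Ground truth is available in two forms: the rendered image with an
interior-only label map, and a feature table synthesized directly from the
planted geometry (`synthetic_object_table()`), which makes every planted
object observable to the filtering stages independently of the raster path.
The recovery checks for ring detection, void removal and tissue typing run
on these tables (20 generations with 4–7 bands; 10 default generations);
the raster path is validated by the watershed/component oracle, the
label-map diameter recovery bound (10% on class means) and the
byte-determinism check. These problem sizes are the package's test design.

## Known limitations

- At the default pixel pitch and opening sizes, isolated objects below
  ~19 px cannot survive binarization (see above). In densely packed
  vascular zones of real sections, wall fragmentation merges such cells into
  complexes that the watershed re-splits; in sparse scenes there is nothing
  to merge and small isolated objects are lost. The per-image wall-pixel
  count inherits the same effect (eroded small-cell area is counted as
  background).
- Voids adjacent to the VT/SP transition, where neighborhoods mix cell
  sizes, can escape both the outlier fence and the majority rule; a few
  percent of planted voids survive in the synthetic runs. Misclassification
  of individual voids and cells is inherent to the approach.
- Ring detection needs at least `2 · ring_window_w` cells and rings with
  relief above the noise floor; shallow rings (< 5% diameter contrast) are
  not called.
- The EMD similarity is a descriptive score; with few images per genotype
  the permutation normalization is coarse.
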