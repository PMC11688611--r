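---
title: "Methods: quantifying T-cell polarity in image-based RNAi screens"
author: "polarityscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying T-cell polarity in image-based RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarityscreen)
```

## The assay and its read-outs

T cells stimulated through the LFA-1 integrin (by immobilized
anti-LFA-1 antibody or its ligand ICAM-1) abandon their resting,
round morphology and polarize into a migratory "hand-mirror" shape: an
elongated body with a protrusive leading edge and a trailing uropod,
the nucleus shifted toward the front. An siRNA screen against this
phenotype images fixed, stained cells well by well and reduces each
segmented cell to five shape parameters:

* **1/(form factor)** $= P^2 / (4\pi A)$, a roundness index. It is 1
  for a perfect circle and grows without bound as the outline becomes
  elongated or irregular, so it rises as cells polarize.
* **Nuclear displacement**, the distance between the nucleus centroid
  and the cell centroid. Near zero in resting cells, larger in
  migrating cells as the nucleus moves toward the leading edge.
* **Cell area** $A$.
* **Gyration radius** $\sqrt{\tfrac1n\sum_i \lVert p_i - \bar p\rVert^2}$
  over cell pixels $p_i$, a measure of cell spread
  ($R/\sqrt2$ for a disk of radius $R$).
* **Elongation factor**, the cell's length-to-width ratio, computed
  here as the major/minor axis ratio of the moment-equivalent ellipse
  ($\ge 1$).

All five increase when cells polarize, so knockdowns that block
polarization depress them jointly (the talin-1 phenotype) and
knockdowns that exaggerate polarization raise them.

## Morphometry: numerical choices

**Perimeter.** A raw count of boundary pixel edges converges to $8R$
rather than $2\pi R$ for a disk and would push the roundness index of
a circle to $16/\pi^2 \approx 1.62$. We therefore estimate boundary
length with a four-direction Cauchy–Crofton estimator
(`crofton_perimeter()`): boundary crossings are counted along rows,
columns and both diagonals (diagonal line families have spacing
$1/\sqrt2$), and

$$P \approx \frac{\pi}{8}\Big(N_{0} + N_{90} +
\frac{N_{45} + N_{135}}{\sqrt2}\Big).$$

A rasterized disk of radius 100 px gives $1/(\text{form factor})
\approx 1.006$; the remaining bias is digitization, not estimator
error.

**Elongation.** "Length over width" is ambiguous for irregular
outlines; we use the axis ratio of the ellipse with the same second
central moments as the pixel set, which is rotation-invariant (a
bounding box is not). No 1/12-pixel moment correction is applied; at
the cell sizes the pipeline targets (body radius ≥ ~8 px) the
correction changes the ratio by far less than cell-to-cell noise.

**Nuclear displacement** is reported in length units; dividing by the
equivalent radius $\sqrt{A/\pi}$ is available via
`normalize_displacement = TRUE` for size-independent comparisons. The
unnormalized form is the default because the screen's other parameters
already carry the size signal separately.

**Pooling.** Cells touching the image border are excluded (their
shape is truncated). Cells from all of a well's imaged fields are
pooled and the well profile is the arithmetic mean of each parameter
(median available via `fun = "median"`); a well fails QC when fewer
than `min_cells` (default 20 at desk scale) cells were measured.
Coordinates are pixel centres, origin top-left, x = column, y = row.

## Plate normalization and Z-scores

Raw well means are divided by the mean of the same plate's (and
screen's) six non-targeting `control_siRNA` wells, parameter by
parameter, making every value a fold-change against the plate's own
control and removing plate-to-plate scale drift. Each
(plate, parameter, screen) group is then standardized:

$$Z = \frac{x - \text{mean}}{\text{STDEV}}$$

with mean and SD taken over the plate's QC-passing **library** wells.
Controls are scored against that distribution but excluded from it:
they are the normalization anchor, and including six wells pinned near
1.0 would shrink the SD and inflate every Z. (`include_controls_in_stats`
restores the all-wells convention.) STDEV uses the sample (n−1)
denominator, the convention of spreadsheet-era screen analysis;
`sd_mode = "population"` is available. A robust variant — median and
1.4826·MAD — is provided (`z_variant = "robust"`) for screens where a
heavy hit load or outlier wells would contaminate the classical
moments; the classical form is the default because it is the formula
the scoring system defines. On clean synthetic screens the two
variants select nearly the same hits (hit-set Jaccard ≥ 0.8 in the
test suite).

## The replicate hit rule

A parameter counts as perturbed when $|Z| \ge 1.5$ in at least 2 of
the 3 replicate screens; a gene is a hit when one or more of the five
parameters is perturbed. Two decisions the rule itself leaves open:

* **Sign consistency** across the qualifying screens is required by
  default: a gene scoring +1.6 in one screen and −1.7 in another is
  not a reproducible phenotype. The unconstrained rule
  (`require_sign_consistency = FALSE`) is kept because the plain
  "±1.5 in ≥ 2 of 3" reading corresponds to it, and the null
  calibration below uses that reading.
* **Evaluability.** A gene with usable scores in fewer than 2 screens
  (QC failures) is reported *not evaluable*, never "not a hit".

The phenotype class is `decreased_polarity` when every perturbed
parameter moves down, `increased_polarity` when every one moves up,
and `mixed` otherwise. No multiple-testing correction is applied
beyond the replicate rule — the replicate requirement *is* the error
control in this design.

Under the null, a single screen flags a parameter with probability
$p_1 = 2\Phi(-1.5) \approx 0.134$, so the unconstrained 2-of-3 rule
has per-parameter false-positive rate
$P(\mathrm{Bin}(3, p_1) \ge 2) \approx 4.9\%$. The acceptance suite
verifies the simulator + scorer reproduce this closed form within
Monte-Carlo error.

## The synthetic screen generator

No raw screen data are deposited, so the package ships a generator
that emulates the study design rather than any particular dataset:
triplicate screens, 96-well plates with one siRNA SMARTpool per
library well, six `control_siRNA` wells per plate, one talin-1
(`TLN1`) positive-control well (strong negative effect on all five
parameters) and one `polyL-lysine` reference well (resting, round
cells — the strongest negative shift). Two tiers share one effect
model:

* the **feature tier** draws per-cell parameter values directly
  (fast; used for all statistical testing), and
* the **image tier** rasterizes label-mask TIFFs — elliptical bodies,
  tapering uropod tails, displaced nuclei — so the morphometry stage
  can be exercised end to end.

Per-cell values are lognormal: strictly positive parameters,
multiplicative noise, with clipping so that digitization-impossible
values (elongation or 1/(form factor) below 1) cannot occur. The
default noise scales are artifact choices, stated once and not tuned:
within-well cell-to-cell SD 0.30 on the log scale (~30% CV, typical
of per-cell morphology), between-screen replicate SD 0.06 per gene
and screen (~6%, typical well-level reproducibility of a normalized
assay). Planted hits shift all five parameter means by ±0.25 on the
log scale (—28%/+28%), which is ≥ 3 library-well SDs at the default
50 cells/well; 10% of genes are planted as decreased-polarity and 10%
as increased-polarity hits, mirroring the ~8–11.5% hit-rate regime of
morphology screens of this design. The paper-scale screen seeded
6000–7500 cells per well across 8 fields; the desk-scale default of 2
plates × 96 wells × 3 screens at 50 cells/well keeps the full test
suite in seconds while leaving well-mean sampling error well below
the planted effects.

Determinism: every well, field and cell uses an RNG substream whose
seed is an integer hash of (master seed, plate index, well index,
screen, purpose); the dataset is a pure function of configuration and
seed, and wells are independent.

What the generator does **not** emulate — and hence what passing
tests cannot certify about real data: segmentation errors beyond
boundary jitter, fluorescence intensity and its artifacts, spatial
plate effects (edge rows, gradients), correlated parameter noise
within a cell, and off-target siRNA structure. The B-score/median
polish family of spatial corrections is deliberately out of scope.

## Clustering of morphology profiles

Hit genes (by default) become rows of a gene × (5 parameters × 3
screens) matrix of Z-scores; the three control treatments are
collapsed to one averaged row each per (parameter, screen). Rows are
clustered with average linkage (UPGMA) on Euclidean distance
(correlation distance via `metric = "correlation"`); the metric is a
package choice, recorded here because the clustering procedure we
follow does not fix one. Missing entries (a gene dropped from one
screen) are handled with pairwise-complete distances rescaled by
$\sqrt{n_\mathrm{total}/n_\mathrm{shared}}$, and rows observed in
fewer than half the columns are excluded. Rows are sorted
lexicographically by label before clustering so results cannot depend
on input order.

Leaves are then rearranged by **optimal leaf ordering** (the
Bar-Joseph dynamic program): among the $2^{n-1}$ orderings reachable
by flipping subtrees, the one minimizing the summed dissimilarity of
adjacent leaves. The test suite verifies the DP against exhaustive
enumeration for n ≤ 8. Ties in the DP break toward the first
(lexicographically earliest) candidate, so trees are reproducible.
The dendrogram is exported as Newick with branch lengths equal to
merge-height differences (tip-to-tip path length = twice the
cophenetic distance), with children rotated to match the leaf order.

## Track metrics

For live-cell validation assays, tracks of centroids sampled at a
fixed frame interval (50 s in the motivating assay) reduce to:
velocity = net start-to-end displacement over elapsed time; origin of
distance = the straight-line distance from the starting point to the
object (reported at the final point; a per-frame series via
`per_frame = TRUE`); speed = summed frame-to-frame path length over
elapsed time. Speed ≥ velocity always (triangle inequality), with
equality exactly on straight constant-rate paths. "Directionality"
is read as net displacement — the standard convention in tracking
software — and this reading is a documented package choice, not a
claim about the original tracker's internals. Tracks shorter than a
configurable minimum duration are excluded from population summaries.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
out <- file.path(tempdir(), "screen-demo")
man <- run_pipeline(list(seed = 1), out)
str(man$recovery)
```

The manifest records the config hash, seed, per-stage timings and
warning counts, md5 checksums of every data output (identical across
reruns with the same config), and the sensitivity/specificity of hit
recovery against the planted truth table.

## Known limitations

* The morphometry consumes label masks; it does not segment. Upstream
  segmentation quality bounds everything downstream.
* The classical Z-score assumes most library wells are phenotypically
  null; screens with very high hit loads compress Z for true nulls
  and the robust variant should be preferred.
* Desk-scale defaults trade statistical resolution for speed; effect
  sizes below ~2 well-SDs are not reliably recovered at 50 cells/well
  and 176 genes, and none of the defaults should be read as estimates
  of any particular screen's noise.
* The optimal-leaf-ordering DP is $O(n^3)$ in the number of clustered
  rows; it is intended for hit lists (tens to a few hundred genes),
  not genome-scale matrices.
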