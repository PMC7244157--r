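---
title: "Quantifying Schwann-cell purity and proliferation from cytospin images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Schwann-cell purity and proliferation from cytospin images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytospinr)
```

## The measurement problem

Primary Schwann-cell (SC) cultures are always contaminated by fibroblasts
(FBs) from the surrounding connective tissue, and both the culture purity
(fraction of cells that are SCs) and the SC proliferation rate must be
demonstrated for every culture used in experiments.  Cytospins --
cell suspensions centrifuged onto a slide -- need only about 10^4 cells
and yield separated, uniformly rounded cells that are well suited to
automated analysis.  The staining panel this package analyses has four
channels:

* **DAPI** stains every nucleus;
* **SOX10** is a transcription factor confined to SC nuclei (FBs and
  mitotic nuclei are SOX10-negative) and serves as the SC identity
  marker;
* **EdU** is a thymidine analogue incorporated during DNA synthesis and
  marks proliferating nuclei;
* **vimentin (VIME)** is an intermediate filament expressed by SCs and
  FBs alike and marks the cell body, which is used purely as a quality
  control: cytocentrifugation occasionally bursts cells, and a cell
  without an intact body must not be counted.

The pipeline counts, per image, the nested populations

> real cells (intact nucleus + intact body)  ⊇  SOX10⁺ real cells (SCs)
> ⊇  SOX10⁺/EdU⁺ real cells (proliferating SCs)

and reports *purity* = 100 · SCs / real cells and a *proliferation rate*
= 100 · proliferating SCs / denominator (see "Open design choices").

## The procedure

### Intact nuclei

The DAPI channel is smoothed with a Gaussian (the smoothing scale of
1.3488 maps to σ = 1 px; the scale is divided by 1.3488 so the parameter
can be stated exactly as in the original configuration) and thresholded
globally with a two-class Otsu method on a 256-bin histogram: this suits
cytospin images, which have a uniform dark background.  Because staining
intensity varies between preparations, the threshold is multiplied by a
correction factor of 0.7 (downwards = more lenient) and clamped to the
configured bounds (defaults 0 and 1).

Touching nuclei are declumped by *shape*: the binary mask is converted to
its Euclidean distance transform, smoothed, and local maxima become
object seeds.  Maxima closer together than the minimum object diameter
(16 px) are suppressed greedily in descending-value order.  Dividing
lines are drawn by synchronous ring growing: labels advance one
8-connected pixel layer per iteration inside the mask, and when two
labels reach a pixel in the same iteration the lower label wins -- a
deterministic realization of repeatedly attaching unassigned pixels to
the adjacent object.  Holes are filled per object, objects outside the
16--60 px equivalent-diameter gate (2·sqrt(Area/π)) are removed, and
objects cut by the image border are removed, since only whole nuclei may
be measured.

Burst nuclei are excluded by circularity.  For every object the
FormFactor

> FormFactor = 4π · Area / Perimeter²

is computed (1 for a perfect circle) and objects below 0.599 are
discarded; the survivors are the *real nuclei*.

### Marker classification

The mean SOX10 intensity (average pixel intensity over the object, on
intensities normalized to [0, 1] by the maximum representable value of
the source bit depth) is measured for every real nucleus.  Because
absolute staining intensity varies by donor and preparation, the
positivity threshold is an operator-set parameter per cytospin; the
package renders the per-nucleus mean intensities onto the image to
support that choice, and `suggest_threshold()` can propose a two-class
Otsu split of the values (an extension beyond the manual workflow;
applied automatically only when `auto_suggest` is set).  EdU positivity
is assessed the same way but asserted *only within* the SOX10⁺ subset,
so the nesting EdU⁺ ⊆ SOX10⁺ ⊆ real nuclei holds by construction.  All
threshold comparisons use `>=` ("minimum value"), so borderline objects
are kept consistently.

### Intact cells

VIME⁺ cell bodies are segmented by seeded propagation: the VIME channel
is thresholded (Otsu, correction 0.9), and every foreground pixel is
assigned to the real nucleus minimizing an accumulated path cost over
8-connected steps,

> cost(p → q) = sqrt( (I(p) − I(q))² + λ · d(p,q)² ),

with d the Euclidean step length (1 or √2) and λ = 0.1 the
regularization factor.  Small λ lets intensity gradients place the
dividing lines (borders fall where the local appearance changes);
large λ approaches the pure nearest-seed geodesic partition.  At λ = 0.1
segmentation is predominantly distance-based, which suits the
homogeneous cell distribution of cytospins.  Bodies touching the border
are kept (their nuclei were already required to be whole).  A body then
survives quality control iff Area ≥ 28 px², FormFactor ≥ 0.35 and mean
VIME intensity ≥ 9·10⁻⁶; nuclei whose body fails are dropped from the
final counts.  This removes cells whose body burst during
centrifugation.

### Reporting and validation

Counts are exported as tab-delimited text (with a CSV twin), overlays
show red/green classification and consecutive object numbering, and the
automated counts can be compared against manual counts with a paired
t-test (two-sided, significance at p < 0.05).  The original description
labels this test "non-parametric", which is contradictory; the standard
parametric paired t-test is implemented as named.  Zero-variance
differences, on which `t.test()` errors, are handled by convention:
all-zero differences give t = 0, p = 1; constant nonzero differences
give t = ±Inf, p = 0.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_diameter`, `max_diameter` | 16, 60 | px | equivalent-diameter gate for nuclei; also the maxima-suppression distance |
| `smoothing_scale` | 1.3488 | -- | pre-threshold Gaussian; σ = scale/1.3488 px |
| `threshold_correction` (primary) | 0.7 | -- | multiplies the Otsu threshold (lenient, tolerates staining variation) |
| `threshold_bounds` | 0, 1 | intensity | clamp on the corrected threshold |
| `min_form_factor` | 0.599 | -- | circularity cut separating intact from burst nuclei |
| `distance_smoothing` | max(1, min_diameter/7) | px | σ for the distance-transform smoothing before seed detection |
| `threshold_correction` (secondary) | 0.9 | -- | VIME foreground threshold correction |
| `regularization_lambda` | 0.1 | -- | distance/intensity balance of the propagation cost |
| `min_body_area` | 28 | px² | minimum intact-body area |
| `min_body_form_factor` | 0.35 | -- | minimum intact-body circularity |
| `min_body_mean_intensity` | 9e-6 | intensity | minimum VIME mean of an intact body |
| `sox10_min_mean_intensity`, `edu_min_mean_intensity` | operator-set | intensity | marker positivity cut-offs per cytospin |

## Numerical choices

* **Otsu histogram**: 256 uniform bins over [0, 1]; between-class
  variance evaluated at bin midpoints; the threshold is reported at the
  upper edge of the selected bin and foreground is strictly above it;
  ties break toward the lowest bin.  A constant image returns the
  constant with empty foreground (no threshold exists that separates
  anything, and a lenient correction factor must not turn the whole
  frame into foreground).
* **Distance-map smoothing**: the automatic filter derived from the
  object diameter is not specified numerically in the original
  description; σ_d = max(1, min_diameter/7) suppresses sub-nuclear
  maxima at the stated size gate and is exposed as a parameter.
* **Perimeter estimator**: the boundary chain (Moore tracing) weighted
  with corner-corrected step lengths (0.948 straight, 1.340 diagonal).
  Raw pixel-edge counting would bias the FormFactor of ideal disks down
  to ≈ 0.78 and corrupt the semantics of the 0.599 cut-off; with this
  estimator rasterized disks of radius ≥ 10 px measure within a few
  percent of 1.  FormFactor is not clamped at 1 (small rasterized
  objects can slightly exceed it).  Objects of 1--2 px get perimeter
  ≥ 1 by convention.
* **Determinism**: maxima suppression orders candidates by descending
  value, then row-major position; ring-growing conflicts resolve to the
  lower label; propagation cost ties resolve to the lower seed label,
  then row-major order.  Seed pixels are frozen in the propagation --
  they keep their own label even below threshold; without freezing, a
  λ = 0 propagation over uniform intensity would relabel whole seed
  regions to the lowest label in the component.
* **Coordinates**: row-major, 0-based, pixel-center convention
  throughout.

## The synthetic generator

Real donor images are not publicly deposited, so validation rests on a
generator that emulates the phenomenology the pipeline assumes:
rounded, well-separated nuclei (radially perturbed disks, FormFactor
≥ 0.7, equivalent diameter inside the 16--60 px gate); cell bodies as
larger disks around each nucleus; SOX10/EdU rendered bright only inside
positive nuclei with a separation that exceeds 5× the noise SD; burst
nuclei as star polygons whose circularity falls below 0.599; clumped
pairs as two overlapping nuclei at 1.2--1.6× radius center distance, so
a detectable indentation exists; border-touching cells cut by the frame;
additive clipped Gaussian noise; no illumination gradient (the global
threshold assumes a uniform background).  One generator is seeded per
call and all draws occur in a fixed documented order, so identical
spec + seed is bit-identical.

Two generator choices deserve justification:

* **Burst bodies are deformed, not absent.**  With additive noise, a
  body-less nucleus would still yield a propagated object (its own
  seed) whose VIME mean (≈ the half-normal noise mean) far exceeds the
  9·10⁻⁶ intensity floor, and whose area and shape pass -- only the
  shape route of the quality control is robust to noise.  Burst bodies
  are therefore rendered as thin-spiked stars whose propagated object
  has FormFactor well below 0.35 (the spike count is calibrated so the
  class separates cleanly from the cut-off).
* **Nucleus radii default to 14--18 px.**  Clumped pairs sit at
  1.2--1.6× radius; with smaller nuclei the pair separation would fall
  below the 16 px maxima-suppression distance implied by the minimum
  object diameter, and the declumping the generator is supposed to
  exercise would be impossible by construction.

What passing tests do **not** show about real data: the generator has no
point-spread function, no illumination gradients, no staining
background structure, no out-of-focus debris, and its intensity classes
are well separated -- real cytospins need the operator-set marker
thresholds precisely because that separation is not guaranteed.
Recovery results on synthetic images validate the algorithmic chain,
not the biological thresholds.

## Open design choices

* **Proliferation denominator.**  The published figures label the
  proliferation panel as a percentage of SOX10⁺/EdU⁺ *real cells* while
  the text calls it an "SC proliferation rate", which could equally mean
  a percentage of SCs.  The default is `real_cells`;
  `proliferation_denominator = "sox10_cells"` selects the other reading.
* **Propagation cost functional.**  The cited propagation algorithm is
  described qualitatively (distances as sums of absolute differences in
  an 8-connected neighbourhood, λ balancing distance against
  intensity).  The implemented step cost sqrt(ΔI² + λ·d²) reproduces
  both limiting behaviours (λ → 0 intensity-dominated, λ large
  distance-dominated) and is verified exactly against a brute-force
  multi-source shortest-path solver, tie-breaks included.
* **Stage order.**  Marker classification runs before body filtering,
  and the final counts intersect with `has_intact_body`, matching the
  original module order (marker filters precede the secondary-object
  modules).

## Problem sizes used in the tests

The validation suite measures ground-truth recovery on 20 synthetic
images of 100 cells (1024×1024 px) at the default degradation mix -- 10%
burst nuclei, 10% burst bodies, 10% clumped, 5% border-touching --
requiring each image's real-cell count within 2 cells and purity and
proliferation within 2 percentage points of truth.  Oracle equivalence
uses 100 random images for the Otsu threshold (exact bin agreement) and
50 random images up to 64×64 px with up to 5 seeds and
λ ∈ {0, 0.1, 1} for the propagation (exact label agreement).  The
acceptance script simulates a three-donor batch, mirroring the
three-donor validation design of the original study.

## Known limitations

* Single-plane 2-D grayscale TIFF/PNG only; no proprietary microscope
  formats, z-stacks, illumination correction or channel registration.
* Global thresholding assumes a uniform background; images with strong
  gradients need preprocessing upstream.
* The declumping seed detector assumes roughly convex nuclei; long
  chains of more than two clumped nuclei may undersegment.
* The 0.599 and 0.35 circularity cut-offs are defined relative to this
  package's perimeter estimator; a different estimator shifts the
  effective cut-off slightly (both remain configurable).
* Marker thresholds are per-cytospin operator decisions; no learned or
  histogram-matching classification is attempted.
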