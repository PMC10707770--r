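---
title: "Quantifying stone cell clusters in pear flesh: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stone cell clusters in pear flesh: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Pear flesh is a matrix of thin-walled parenchyma cells in which groups of
sclereids — stone cells — differentiate early in fruit growth. A stone cell
forms when a parenchyma cell deposits a lignified secondary wall;
lignification proceeds inward (a partially lignified cell shows a stained
*ring* around a surviving lumen, a mature cell is stained solid), and once it
starts, the cell stops expanding. Clusters grow by accretion: new sclereids
differentiate around earlier ones, so cluster centers are mature while the
periphery is still ring-stage. Parenchyma, by contrast, keeps expanding until
harvest. The consequence is a purely geometric *dilution*: stone-cell
material is fixed early, the tissue around it keeps growing, and the area
fraction and count density of clusters fall over development even though no
cluster is lost.

The quantities of interest, per section and per concentric flesh zone, are:
the percentage of tissue area occupied by stone cell clusters (SCCs), SCCs
per cm², SCC size, stone cells per SCC, mean stone cell size, the share of
isolated stone cells, and parenchyma size and circularity split by contact
with clusters. The operational definitions are:

* **SCC**: more than three adjoining stone cells.
* **Isolated**: a single stone cell or a group of two or three, separated
  from other stone cells by at least one parenchyma cell.
* **Circularity**: ratio of a cell's Feret (caliper) diameters, in (0, 1],
  with 1 a circle. The index is stated in the source literature both as
  "largest/smallest" and as a 0–1 scale with reported values well below 1;
  only smallest/largest satisfies the scale and the interpretation, so the
  package computes `c = d_min / d_max`.

## Pipeline model and assumptions

**Stain separation.** Sections stained with safranin and fast green show
lignified material in a red hue family and unlignified walls in blue. Pixels
are classified in HSV space: saturation below `saturation_min` (default
0.20) is background (lumina, cytoplasm); saturated pixels are lignin if hue
is within `lignin_hue_halfwidth` (default 0.12) of red, wall if in the blue
band (default hue 0.45–0.85), otherwise background. The rule assigns every
pixel to exactly one class. It assumes reasonably white-balanced brightfield
images; no cross-batch stain normalization is attempted.

**Stone cell instances.** Connected lignin regions are cluster fragments,
not cells: adjoining stone cells share lignified walls. Two sources of
boundary evidence are used, in order. (1) *Seams*: the lignified wall
between two stone cells is optically denser (darker) than the cell bodies;
lignin pixels with HSV value below `seam_value_max` (default 0.62) are
removed before labeling, which separates the cells of a cluster. (2)
*Watershed fallback*: a component with no adjacent seam evidence that is
solid (not ring-shaped) and larger than 2.2× the median component size is
split by a watershed on its distance transform, with tolerance
`1 + 0.2 * max(distance)` so single convex cells are not fragmented.
Ring-stage cells are detected by a filled-to-stained area ratio above 1.25
and are closed by hull filling, so their measured area is the whole-cell
area — consistent with mature cells, whose wall fills the lumen. Instances
below 150 µm² are discarded as debris.

**Parenchyma instances.** Each enclosed unstained region not occupied by a
stone cell is one lumen; the measured "internal size" excludes the wall
band. This presumes closed wall boundaries, which holds on the synthetic
renders; on real images broken walls would merge lumina, which is a known
limitation. Instances touching the field border are flagged and excluded
from per-cell size/shape statistics (their geometry is truncated) but their
pixels still count toward area fractions.

**Grouping.** "Adjoining" is implemented as pixel sets within a Chebyshev
distance of `adjacency_px` (default 3 px = one 2-px wall band plus one) of
each other; groups are connected components of that adjacency graph, and the
>3 rule classifies them. With the default geometry, distinct groups are
separated by at least one parenchyma cell (≈ 15 px), far beyond the
adjacency tolerance, so truth group identity is unambiguous. Groups touching
the border count for presence metrics (% area, count) but are excluded from
size and cells-per-SCC statistics.

**Contact classes.** A parenchyma cell is "around cluster" if its lumen
comes within one wall-band dilation of an SCC member pixel. Isolated stone
cells do not confer the status, since the class is about clusters.

**Zones and global values.** Sections arrive tagged In/Md/Ex, or a sector
mask is partitioned into three bands of equal radial extent
(`partition_zones()`, radial when an apex origin is supplied, else along the
sector axis). Global values "consider the proportional area contribution of
each zone": the default weights each metric by its natural pooled
denominator — analyzed area for presence metrics, cluster counts for
per-cluster metrics, cell counts for per-cell metrics — which makes every
global value identical to a single-pass computation over the pooled images
(a property the tests assert to machine precision). A `geometric` mode
accepts externally supplied zone areas (e.g. annulus areas of the whole
fruit) instead; which weighting the original workflow used is not
documented, so both are provided with the pooled-identity default.

**Texture.** The SCC "diameter" for texture classes is the equivalent-circle
diameter `2*sqrt(A/pi)`, since area is what segmentation measures directly.
Boundaries: coarse/gritty requires *exceeding* 250 µm and highly-soft
requires *less than* 150 µm, so both boundary values (150, 250) fall in the
middle class.

## Statistics

Percentages (area occupied; isolated-to-clustered cell ratio) are
arcsine-transformed (`asin(sqrt(p))`) before ANOVA. The design — zones as
repeated measures nested within fruits, fruits nested in treatment (and
stage) — implies a split-plot error structure, and no model formula is
documented for the original workflow, so the package fixes one:

* treatment, stage and their interaction are tested against the
  **between-fruit** stratum (fruit means; the fruit-level residual is the
  error term);
* zone and its interactions with the between factors are tested against the
  **within-fruit** stratum (fruit fitted as a block).

Replicate images within a fruit × zone cell are subsamples and are averaged
first. On balanced designs this reproduces the exact split-plot sums-of-
squares decomposition (asserted against a hand-computed oracle); unbalanced
designs (fewer fruits at the harvest stage) use Type-II sums of squares as a
fixed convention. Sphericity is assumed (the upstream workflow tested for
it); no epsilon correction is applied. A constant response is flagged
degenerate with NaN statistics rather than an error. Empirically, the
treatment test holds its nominal type-I error under a null simulation at the
Stage-I design size, and detects a two-residual-SD treatment effect with
power above 0.9 (both computed in the test suite).

Tukey HSD uses the studentized range with the Tukey–Kramer standard error
for unequal group sizes. The compact letter display assigns one letter per
*maximal clique* of the non-significance graph, which guarantees the
defining property — two groups share a letter if and only if they are not
significantly different — and is checked against brute-force all-pairs HSD.

## The synthetic generator

The generator exists because the pipeline's accuracy can only be audited
against known truth. It emulates the statistical structure the analysis
assumes, not histological appearance:

* **Parenchyma mosaic**: Voronoi tessellation of a jittered hexagonal
  lattice, with a wall band (default 2 px) between neighbors. Mean lumen
  area is controlled by inflating the gross cell area for the wall loss
  (hexagon perimeter ≈ 3.72·√A, irregularity factor 1.12). Circularity is
  controlled by generating the tessellation in an anisotropically scaled
  frame; the scale-to-circularity response was calibrated once on jittered
  mosaics and is inverted by interpolation (unstretched mosaics realize
  ≈ 0.78, so targets above ~0.8 are clamped; the ±0.1 contract holds up to
  ~0.9). Realized statistics, not geometry, are the contract: mean area
  within 15 % and mean circularity within 0.1 of target, verified by
  pixel-counting oracles.
* **Clusters**: the number of SCCs is Poisson at the requested per-cm²
  density; cells per SCC are `4 + NB(mu - 4, size)` so every SCC exceeds
  three cells by construction; per-cell areas are lognormal (CV 0.25)
  around `stone_cell_area_um2`. Each group is carved as a disk footprint
  tessellated into its member cells — deliberately *decoupled* from the
  host parenchyma size, because stone cells stop growing at lignification.
  This is what makes the dilution mechanism reproducible: the same
  stone-cell truth can be planted into a mosaic of fourfold parenchyma area
  (and fourfold field, i.e. the same tissue later in development), and the
  recovered % area and count/cm² must fall fourfold. Footprints keep one
  parenchyma-cell diameter of separation (bounded retries, then a placement
  error) so groups never merge.
* **Lignification**: in `mixed` (Stage-I-like) mode, cells touching the
  footprint boundary are ring-stage and interior cells full, with the
  center-most cell always full — the centre-outward maturation gradient; in
  `full` mode (Stage-II-like) every cell is mature. Isolated cells, the
  earliest-differentiated, are always full.
* **Rendering**: lumina pale, walls blue, stone cell bodies red, ring cells
  a red annulus (~6 µm) around an unstained lumen, and stone–stone walls a
  darker red seam — giving clusters the visually fused appearance that the
  segmentation stage must undo. Additive Gaussian noise (sd 0.015) is
  applied reproducibly from the seed.

All randomness is driven by explicit seeds with local RNG state; identical
parameters and seed give byte-identical truth tables and rasters.

**What the generator does not emulate** — and therefore what passing
recovery tests do not establish for real micrographs: stain variability and
uneven illumination, section folds and debris, broken or incomplete walls,
vascular bundles, non-disk cluster shapes, and clusters invaded by
parenchyma (cells detaching from a cluster). Recovery results on synthetic
data bound the algorithmic error of the pipeline, not its robustness to
acquisition artifacts.

## Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| field size | 2449 × 2449 | µm | the 0.06 cm² square acquisition field |
| `pixel_size_um` | 3 | µm/px | typical camera calibration at low magnification; calibration is a free parameter since none is documented for the source images |
| `mean_parenchyma_area_um2` | 2800 | µm² | end-of-Stage-I general parenchyma (zone means ≈ 2150–3150) |
| `parenchyma_circularity` | 0.65 | — | Stage-I reported range ≈ 0.62–0.68 |
| `scc_density_per_cm2` | 25 | cm⁻² | a Stage-I-like density giving ≈ 1.5 clusters per field |
| `cells_per_scc` | 12 (size 4) | — | mid-range cluster; zone presets span 8–16 |
| `stone_cell_area_um2` | 2000 | µm² | stone cells differentiate from young (small) parenchyma and stop growing |
| `isolated_fraction` | 0.05 | — | isolated stone cells are a small share of all stone cells |
| `wall_px` | 2 | px | walls must be ≥ 1 px for instance separability; 2 px survives downsampling |
| texture thresholds | 150 / 250 | µm | established diameter boundaries for flesh texture classes |
| `alpha` | 0.05 | — | conventional significance level |

`stage_params(stage, zone)` packages the stage × zone presets: Stage I has
the inner-zone gradient (largest, most numerous clusters near the core) and
mixed lignification; Stage II has ≈ 4× parenchyma area, ≈ 1/5 the cluster
density, lower circularity, and full lignification.

## Numerical choices and degenerate inputs

* Feret diameters are computed from the convex hull (rotating-calipers
  width for the minimum), with one pixel width added so diameters measure
  physical extent; 1-pixel instances degenerate to (1 px, 1 px) and are
  excluded from shape statistics with a warning.
* Pixel connectivity is 8-neighbor throughout; the wall band is the set of
  pixels whose Chebyshev-r neighborhood contains another label
  (r = wall_px / 2).
* Non-positive areas, densities, proportions outside their ranges, fields
  smaller than 10 equivalent cell diameters per side, unknown zone labels,
  unknown lignification states, zero analyzed area, and a zero SCC-cell
  denominator in the isolated percentage all raise typed errors rather than
  propagating NaN.
* Ties in the weighted nearest-seed assignment inside cluster footprints
  resolve to the first (lowest-index) seed; group placement retries are
  bounded (default 500) before a placement error.

## Problem sizes used in the automated checks

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: the recovery benchmark analyzes 100 fields (tests) or 60 fields
(acceptance script) of 0.06 cm² at 3 µm/px; the dilution experiment uses
3–4 field pairs; the grouping oracle compares 1000 random 60 × 60 px
fields against brute-force transitive closure; the ANOVA null simulation
uses 2000 (tests) or 1000 (script) replicates at the Stage-I design size
(2 treatments × 9 fruits × 3 zones × 2 images). These sizes are the
package's reporting choices; all are parameters of the respective
functions.

## Known limitations

* The stain-separation thresholds are tuned to the rendering palette family;
  real batches may need threshold adjustment (no automatic stain
  normalization).
* Cells-per-SCC is contracted to ±1 cell: fully lignified clusters with
  weak internal seams are split by the watershed heuristic, which can merge
  or split a cell in rare geometries.
* Zone partitioning of whole-sector masks assumes a single interior apex;
  irregular sector shapes are out of scope (zones normally arrive as
  acquisition metadata).
* The ANOVA implements one fixed error-structure convention; it is not a
  general mixed-model interface.
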