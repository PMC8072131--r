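---
title: "Quantifying the V-SVZ niche in 3D: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the V-SVZ niche in 3D: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemorph)
```

# The measurement problem

The ventricular–subventricular zone (V-SVZ) lines the lateral ventricle
wall and hosts the adult brain's largest neurogenic niche: GFAP+ type B
stem cells sit apically under the ependymal layer and contact a planar
vascular plexus; their progeny — transit-amplifying type C cells and
DCX+ type A neuroblasts — proliferate and migrate along those vessels.
Whole-mount preparations image the entire niche as one 3D explant, and
the biology of interest (vascular remodelling with age and sex, stem-cell
depletion, chain disorganization) is carried by a handful of morphometric
summaries of the segmented channels. This package implements those
summaries as testable estimators and provides the synthetic ground-truth
phantoms to validate every one of them.

Coordinates follow one fixed convention throughout: voxel $(i,j,k)$
(1-based) has its centre at $((i{-}1)d_x,(j{-}1)d_y,(k{-}1)d_z)$ µm and
the $z=0$ face of the grid is the ependymal (apical) surface. Apical
depth of a cell is therefore simply the $z$ coordinate of its centroid;
for real data an explicit surface mask can replace the plane.

# Estimators

## Vessel skeleton, tortuosity, diameter

The laminin mask is thinned by topology-preserving 3D curve thinning: a
border voxel is deleted only if it is a *simple point* (its removal
changes neither the 26-connectivity of the local foreground nor the
6-connectivity of the local background) and not a curve endpoint, in six
directional subiterations per round with re-testing at deletion time.
This guarantees one skeleton component per vessel component. Anisotropic
stacks are first resampled to isotropic spacing (the finest axis, by
trilinear interpolation) because curve thinning assumes isotropy; all
reported lengths stay in µm.

The skeleton decomposes into a graph: voxels of degree ≠ 2 are nodes
(junctions and endpoints), the 26-connected voxel paths between them are
branches, and pure cycles are kept as closed branches. Two numerical
cleanups matter:

- **Spur pruning.** Thinning a thick tube sprouts short side branches
  that would inflate tortuosity. Spurs — branches with exactly one
  degree-1 endpoint hanging off a junction — shorter than
  `prune_factor` (default 2) times their local mean diameter are
  removed, then degree-2 nodes are merged, iterating to a fixed point.
- **Centreline smoothing.** A digital 26-connected path systematically
  overestimates the length of a smooth curve (up to ~8% at unlucky
  orientations), which would bias tortuosity upward beyond its
  tolerance. Branch centrelines are therefore smoothed with a short
  moving average (`smooth_window`, default 5 voxels, endpoints fixed)
  before the path length is summed. A straight line is invariant under
  this smoothing, so the straight-tube anchor (τ = 1) is unaffected.

Per branch, tortuosity is the smoothed path length over the endpoint
chord; closed branches (coincident endpoints) return `NA` and are
excluded from medians. On phantoms, a straight tube yields τ = 1.000, a
semicircular tube recovers π/2 within 2–3%, and a sinusoid matches an
independent quadrature oracle within 1%.

The diameter at a skeleton voxel is twice the inscribed-ball radius read
off the Euclidean distance transform of the mask. One numerical choice:
the distance transform measures to the nearest *background voxel
centre*, while the mask boundary lies about half a voxel closer, so the
radius is corrected by half the voxel pitch (floored at half a voxel).
Uncorrected, a true 9 µm tube measures exactly 10.0 µm and would be
misclassified against the 10 µm capillary cutoff; corrected, phantom
tubes of true diameter 6 and 9 µm measure 5.3 and 9.0 µm, and capillary
classification (`d < 10` µm, the field's convention) is stable. The
uncorrected literal estimator remains available via
`branch_diameter(correction_um = 0)`.

Because published diameter distributions do not say whether the unit is
a branch or a skeleton voxel, `diameter_distribution()` exposes both
weightings and the Kolmogorov–Smirnov comparison consumes either.

## Densities

Vessel density is vessel voxel volume over V-SVZ volume; chain density
is DCX voxels over V-SVZ voxels, optionally within an ROI mask (the
"anterior" region is an explicit mask input, never inferred anatomy).
The V-SVZ volume itself has no published construction, so the package
defines it deterministically: the union of all stained channel masks,
morphologically closed (ball radius `closing_radius_um`, default 5 µm)
and hole-filled per z slice — always a superset of every channel mask. A
user-supplied mask, or the whole grid (`niche = "full"`, the natural
convention for slab phantoms that fill the field of view), can replace
it.

## Chains and eccentricity

DCX chains are 26-connected components above a minimum volume. Chain
shape is summarized by eccentricity $e = 1 - p_{mid}/p_{max}$ from the
principal components of the µm-scaled voxel cloud: 1 is a line, 0 a
circle or sphere. "Principal component" is interpreted as the standard
deviation along each principal axis (the square root of the covariance
eigenvalue), because that makes a solid ellipsoid with semi-axes
$a \ge b \ge c$ yield the intuitive $e = 1 - b/a$; raw eigenvalues are
offered as `convention = "eigenvalue"`. The two conventions agree
exactly on the line and circle anchors, which is also why those anchors
make good acceptance quantities. Eigenvalues below $10^{-12}$ of the
largest are treated as exact zeros so that rounding noise cannot pull
the line anchor off 1 through the square root. Eccentricity is invariant
under rigid motion and uniform scaling (verified to $10^{-9}$).

## Cells: colocalization, apical filter, counts

Nuclei are DAPI components within a volume window. GFAP positivity is
binary-mask overlap: a cell is GFAP+ when at least
`gfap_overlap_fraction` (default 0.3, boundary inclusive) of its nucleus
voxels fall inside the GFAP mask — the published analyses state
"overlap" without a fraction, so the threshold is a surfaced
configuration knob; 0.3 tolerates partial halos, and raising it can only
remove positives. Ki67 uses the same rule. The apical stem-cell pool is
the GFAP+ subset with apical depth ≤ 5 µm (the field's "within 5 µm of
the ependymal layer" rule; the threshold is configurable). Counts accept
an optional ROI mask and use centroid membership.

## Proximity

The vessel surface is operationalized as the vessel foreground mask
itself — laminin stains the basement membrane, i.e. the surface — and
distances are an anisotropy-aware exact Euclidean distance transform of
its complement (lower-envelope algorithm, verified voxel-for-voxel
against brute force). Cell distances come in `"surface"` (minimum over
nucleus boundary voxels; default) and `"centroid"` modes — surface never
exceeds centroid, and published cell–vessel distances do not specify
which was used, so both are exposed. Chain distances are always
surface-to-surface (minimum of the map over boundary voxels of the
chain); a chain overlapping the vessel mask reports 0 with a warning.

## Time-lapse population slope

In-vitro recordings (defaults mirror a 4-day experiment: 980 frames
every 5 min) are reduced to per-frame cell counts (2D threshold +
minimum-area components; constant frames count 0 and are flagged) and
the ordinary least-squares slope of count versus frame index — identity
tracking is deliberately not required for this statistic. The slope is
also reported per hour via the interval. $R^2$ of a zero-variance series
is 0 by convention. The regression runs on frame index rather than
elapsed time; the two differ only by the interval scale factor, which
the per-hour conversion restores.

The phantom's birth–death simulator records as truth the OLS slope of
the exact expected trajectory $n_0(1+p_{div}-p_{death})^t$. By linearity
of least squares this equals the expectation of the fitted slope, and it
reduces to the familiar linear-regime value $n_0(p_{div}-p_{death})$
when `frames × net rate` is small; at the Monte-Carlo settings used in
the tests (200 frames at net rate 0.005) the exact form is ~0.84
cells/frame versus 0.5 for the linear approximation, so the exact form
is the honest oracle.

## Group statistics

Skewed per-object metrics (tortuosity, diameter, eccentricity) are
summarized per sample by the median and compared with the Wilcoxon
rank-sum test: midrank ties, exhaustive enumeration of all
$\binom{n_A+n_B}{n_A}$ assignments when $\min(n_A,n_B) \le 8$ (exact
even under ties), and the tie-corrected, continuity-corrected normal
approximation otherwise. Densities and counts use mean ± SEM summaries
and the two-way ANOVA (age × sex) with type-II sums of squares —
appropriate for the mildly unbalanced 4–6-animals-per-group designs —
computed by linear-model comparison so that degenerate designs behave
sensibly: identical values give all $F = 0$, and an additive zero-noise
design gives unbounded main-effect $F$ reported as $p \to 0$ with an
interaction $F$ of 0. Diameter distributions are compared with the
two-sample Kolmogorov–Smirnov test (exact ECDF gap, asymptotic p).
Post hoc adjustment offers Sidak ($p' = 1-(1-p)^m$) and Tukey's
studentized-range comparisons; published figures alternate between the
two without a stated rule, so the pipeline selects per metric, and the
report labels object-level versus per-animal results explicitly to keep
the unit of inference (and pseudo-replication risk) visible.

# The phantom: what it emulates, and what it does not

The generator rasterizes analytic geometry with a voxel-centre-in-object
rule (no antialiasing), which is what makes volume-fraction truths
computable and voxelization tolerances statable (±10% relative for the
sizes used here). Tube centrelines are parametric (straight, sinusoid,
helix, semicircular arc) with analytic tortuosity; nuclei are spheres
with optional GFAP shells and Ki67 co-labelling placed to honour
requested apical depths and vessel-surface distances (solved from the
local tube geometry, then re-verified analytically against all
centrelines); chains are ellipsoids with known semi-axis ratios. Objects
are kept mutually disjoint so connected-component analysis recovers them
one-to-one. Default tube axes snap to the voxel-centre lattice: an axis
midway between voxel centres hits the worst-case cross-section
digitization (a 3 µm-radius tube loses ~29% of its cross-section voxels),
which would break the stated volume tolerances for thin tubes; explicit
fractional placements remain available. Intensities are two-level
(background/foreground) plus additive Gaussian noise, rounded to 16-bit
integers — the simplest model that exercises thresholding, and it makes
seeded output bit-identical.

What the phantom deliberately does **not** model: microscope point-spread
functions, depth-dependent attenuation and bleaching, tile stitching
artifacts, touching or overlapping somata, non-spherical nuclei, and
intensity texture inside objects. Passing the recovery suite therefore
demonstrates correctness of the estimators on clean geometry — it does
not certify segmentation performance on real stacks, where thresholding
and object separation are the dominant error sources.

# Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `apical_um` | 5 | µm | apical type B filter depth |
| `capillary_um` | 10 | µm | capillary classification cutoff |
| `gfap_overlap_fraction` | 0.3 | — | nucleus∩GFAP fraction for GFAP+ |
| `closing_radius_um` | 5 | µm | niche-mask closing ball |
| `prune_factor` | 2 | ×diameter | skeleton spur prune length |
| `smooth_window` | 5 | voxels | centreline smoothing window |
| `connectivity` | 26 | — | component connectivity (tubes/chains need diagonals) |
| `eccentricity_convention` | `"sd"` | — | PC = sd (default) vs raw eigenvalue |
| `cell_distance_mode` | `"surface"` | — | cell-to-vessel distance mode |
| `diameter_weighting` | `"per_branch"` | — | diameter-distribution unit |
| `niche` | `"union"` | — | V-SVZ volume construction |

Segmentation defaults to Otsu thresholding (strictly-above rule) with
optional Gaussian pre-smoothing and morphological opening; a fixed
threshold is available. Constant-intensity inputs raise an error rather
than guessing.

# Problem sizes and validation scope

The test and validation suite runs phantoms of roughly 100×80×30 voxels
at 1 µm spacing (one to two vessels, tens of cells, a few chains),
100 random ≤25³ grids for exhaustive brute-force distance-map
comparison, 50-seed Monte-Carlo calibration of the population slope at
$n_0 = 100$, 200 frames, and 10,000 null replicates for the rank-sum
type-I error (0.05 ± 0.01 at $n = 20$ per group). These sizes keep the
whole battery at a few minutes on one CPU while leaving every tolerance
meaningfully exercised; all estimators are resolution-independent, so
conclusions transfer to larger fields of view.

# Known limitations

- Curve thinning can land the skeleton a voxel off the continuous medial
  axis, so branch diameters inherit roughly half-voxel uncertainty; at
  1 µm spacing that is the dominant term in the ±1 µm diameter
  tolerance.
- Distances are Euclidean, not geodesic within tissue.
- The niche-volume construction is a package convention (the published
  denominator is undefined); comparisons across pipelines should fix it
  explicitly.
- The Wilcoxon normal approximation is used above group size 8; exact
  enumeration beyond that is combinatorial and unnecessary at published
  group sizes.
- Lineage tracking, mitosis detection and cell-fate classification are
  out of scope; the population slope intentionally needs only counts.
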