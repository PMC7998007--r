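---
title: "From MR volume to printable model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MR volume to printable model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(neuroprint)
```

`neuroprint` implements the computational core of a patient-specific brain
tumor model workflow: interactive seeded segmentation of MR volumes,
multiplanar quality control, watertight surface extraction for 3-D printing,
surgical-planning scores, and the contingency statistics used to validate
the models' clinical usefulness. This vignette documents the methods and
every numerical choice a reader would need to reproduce or audit the
results.

## Image model and I/O

An `image_volume` is a 3-D numeric array plus geometry: voxel `spacing`
(mm), `origin` (mm) and a `direction` matrix with orthonormal columns.
World coordinates follow the LPS convention; voxel indices in the public
API are 0-based with x fastest. NIfTI files are read through RNifti and
written as 64-bit floats with a NIfTI-2 header so that a write/read round
trip is bit-exact (NIfTI-1 headers store geometry as float32, which loses,
for example, a 0.8 mm spacing). DICOM series are read by a minimal parser
(Explicit/Implicit VR Little Endian, uncompressed single-frame): slices are
sorted by the projection of Image Position (Patient) onto the slice normal,
a heterogeneous series UID is a format error, and non-uniform slice gaps
(relative tolerance 1e-3) are a geometry error. Volumes whose direction is
an axis permutation/flip are canonicalized by relocation without
interpolation; genuinely oblique volumes are resampled trilinearly.

Denoising offers a median filter (cross kernel; at the borders the
neighbourhood is truncated, which is what reproduces the documented
`[0, 10, 0] -> [0, 0, 0]` line case) and Perona–Malik anisotropic diffusion
(default 5 iterations, conduction `kappa = 30`, `dt = 0.1`, stable since
`dt <= 1/6` for 6 neighbours).

## Seeded graph-cut segmentation

Seeds are drawn as `polygon`, `sketch` or `freedraw` geometries on axis
slices, rasterized boundary-inclusively (even-odd rule at voxel centres;
strokes as 8-connected digital lines, dilated by a Chebyshev disc of
`brush_radius`). Foreground/background conflicts at a voxel are an error,
not a silent override.

Segmentation minimizes the classic two-terminal energy: n-links between
6/18/26-neighbours carry `exp(-(I_p - I_q)^2 / (2 sigma^2))`, divided by
the inter-voxel distance in mm when `spacing_aware` (the default;
`sigma = 30`). Seeds are hard constraints via terminal links of capacity
`K = 1 + max_p sum of n-links at p`, which exceeds any achievable cut, and
an optional Gaussian-likelihood regional term (`lambda_regional`, default
0) is clamped to `[0, K]`. The minimum cut is computed exactly by a Dinic
max-flow in C++; on volumes small enough to enumerate every labeling, the
returned energy equals the exhaustive minimum in 20/20 random trials (this
is an acceptance check). One binary cut runs per structure; the resulting
masks are assembled into a label map by strict priority ranks (duplicate
ranks are a configuration error), so the output is disjoint by
construction. Seeded region growing (per-generation running mean) and Otsu
thresholding (256 bins, threshold at the upper edge of the argmax bin) are
provided as simpler alternatives.

## Multiplanar reconstruction

Oblique planes are defined by origin, unit normal and in-plane axis
(orthogonality checked to 1e-6); slices are sampled trilinearly. For
axis-aligned planes the sample steps equal the in-plane voxel spacings, so
extraction is bit-identical to direct slice indexing — the quality-control
images show exactly the data the cut was computed on. Label contours are
traced by 2-D marching squares at level 0.5 on a nearest-neighbour label
resample (labels must not blend); contours are closed polylines in 0-based
pixel coordinates, so a solid pixel block `p..q` is enclosed by
`[p - 0.5, q + 0.5]`.

## Surface extraction and export

Surfaces are extracted at level 0.5 from binary masks by marching
**tetrahedra** on the Kuhn 6-tetrahedron split of each lattice cell. The
tetrahedral variant was chosen over the 256-case table version because it
is watertight and consistently outward-oriented by construction and
measured slightly better on the volume-fidelity bound (digital ball of
radius 10: 0.30% volume error versus 0.51% for the table version; the
requirement is 2%). Vertices sit at edge midpoints and are welded by
integer key, optional Laplacian smoothing (`lambda = 0.5` per iteration)
preserves connectivity. `is_watertight` checks that every undirected edge
is shared by exactly two opposed directed edges, all faces have nonzero
area, and the signed volume is positive. Binary STL follows the printer
format byte for byte: 80-byte header, uint32 triangle count, 50 bytes per
facet — a single-triangle file is exactly 134 bytes.

The two-part external mold subtracts the brain mask from its dilation by
`wall_thickness` and splits the shell at the mask centroid. The default
dilation metric is per-axis Chebyshev (a box kernel, radius
`floor(wall/spacing)` voxels per axis), which makes the voxel accounting
exact: `|dilated| = |brain| + |part1| + |part2|`, e.g. a 10-voxel cube with
a 2 mm wall yields a 14^3 − 10^3 = 1744-voxel shell. A Euclidean
(distance-transform) metric is available as an option; it rounds corners
and gives smaller shells.

## Planning metrics

Tumor depth is the minimum spacing-aware Euclidean distance from tumor to
the brain-mask outer surface (6-neighbour definition), computed with a
Felzenszwalb–Huttenlocher distance transform; contact means depth 0 and
category `cortex`, otherwise `< 20` mm is `intermediate`, `20-40` mm
inclusive is `deep`, `> 40` mm is `very_deep` (the 40 mm boundary is read
as inclusive to `deep`, matching "between 2 and 4 cm"). The craniotomy
size-change score bins `100 |a_3d - a_mr| / a_mr` at 25/50/75 (0-3,
changes past 100% clamp to 3); the location-change score bins the
**Jaccard** overlap at 0.90 and 0.50 (0-2). Jaccard was chosen as the
overlap measure because it is symmetric in the two plans; an
intersection-over-first-plan variant is provided for sensitivity checks
and never reports less overlap than Jaccard.

## Validation statistics

Fisher's exact test enumerates the hypergeometric distribution over the
fixed-margin support (one-sided: upper tail; two-sided: total probability
of tables no more likely than the observed, with a 1e-7 relative slack for
float ties). The 2x2 chi-square uses the closed form
`N(|ad-bc| - yates N/2)^2 / (r1 r2 c1 c2)` with 1 df. Both agree with the
standard R implementations to 1e-8 across random tables, and the
chi-square reference distribution is additionally checked against a
Monte-Carlo permutation null. Display change rates round half-up to one
decimal (`change_rate(1, 16)` is 6.3, where bankers' rounding would give
6.2), matching how such percentages are conventionally reported. For the
experience-group contingency (8 changed of 28 less-experienced versus 2 of
36 experienced), the one-sided exact p is 0.0147.

## Phantom and what it shows

Because no patient data ship with the package, every claim is exercised on
a synthetic phantom: a 64^3, 1 mm isotropic grid with a brain envelope of
mean radius 26 mm modulated by a `2 sin(8 theta) cos(8 phi)` radial
sinusoid (gyri-like non-convexity), a 9 mm hyperintense tumor ball offset
from centre, paired ventricular ellipsoids and a deep nucleus, with class
means 10/100/40/130/160 and additive Gaussian noise. Generation is
bit-reproducible per seed and restores the caller's RNG state. Automatic
seed geometries emulate interactive strokes (foreground discs at least
2 mm inside the structure on three slices; background ring 4-6 mm outside
plus two clear slices). With default parameters the tumor Dice against
ground truth is at least 0.95 at noise sigma 2 and at least 0.85 at sigma
10. The phantom demonstrates algorithmic correctness, not clinical
performance: its contrasts are idealized, and the published clinical
outcomes (case series, reader scores) are not reproducible from code.

## Pipeline

`run_pipeline()` executes the fixed stage order read, denoise, seeds,
segment, resolve_overlaps, mpr_qc, mesh, export under one YAML config
(defaults as above), failing fast on missing inputs before any
computation. It writes the label map (NIfTI), at least three MPR QC PNGs,
one binary STL per structure (`<case>_<name>.stl`, optionally two mold
parts), a run log, and a manifest JSON with per-structure volumes, colors
and md5 checksums of every artifact. Identical configs reproduce
byte-identical STL payloads. The same operations are scriptable through
`inst/cli/neuroprint.R`.
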