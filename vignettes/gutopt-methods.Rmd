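---
title: "gutopt: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutopt: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
decisions taken where the underlying image-processing problem left genuine
choices open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Optical projection tomography (OPT) acquires optical projections of a
cleared, fluorescently stained sample over a full rotation and reconstructs
them into a 3D volume. For tubular intestinal samples this enables mesoscale
screening: villous architecture in the label-free autofluorescence channel,
and sparse structures such as isolated lymphoid follicles (ILFs) in a marker
channel, over millimetre-to-centimetre lengths. Because the follow-up
question is usually histological ("cut the block until you reach the
structure seen in 3D"), the package also keeps the bookkeeping that maps 3D
regions of interest to physical cryosection indices (reverse-OPT).

Everything is developed and validated on synthetic phantoms whose ground
truth is exported, so each stage has a quantitative recovery test.

## Acquisition model and reconstruction

**Geometry.** Parallel-beam projection is assumed, the conventional model
for OPT where the depth of field covers the sample; each slice along the
sample's long axis (array axis 1) is independent. A pixel at centred slice
coordinates $(x, y)$ contributes to detector position
$s = x\cos\theta + y\sin\theta$; the projection integrates along the
orthogonal direction. Angles are $\theta_k = k\,360^\circ/n$,
$k = 0,\dots,n-1$, endpoint-exclusive: opposing views are acquired
redundantly rather than folded to 180°, matching a full-rotation
acquisition. Typical angle counts are 400 or 1200 (0.9° or 0.3° steps). The
rotation axis is fixed at the detector-column centre; no axis-misalignment
correction is modelled.

**Filtered back-projection.** Each detector row is zero-padded to the next
power of two (at least twice its length) to suppress circular wrap-around,
multiplied in the frequency domain by the ramp $2\lvert f\rvert$ (Ram-Lak;
optionally apodised by a Hann window for noisy data), inverse-transformed,
smeared back across the slice with bilinear interpolation, and the
angle-sum is scaled by $\pi/(2\,n_\text{angles})$. Values outside the
inscribed reconstruction circle are not measured by any projection and are
set to zero. Two consequences worth knowing:

* under zero-padded (linear-convolution) semantics a constant profile is a
  boxcar, so the ramp output is near zero away from the boxcar edges but not
  at them — the tests assert exactly that;
* the per-angle line integrals conserve the slice mass only up to bilinear
  resampling error; on disk phantoms this is a fraction of a percent, and the
  acceptance script recomputes it.

**Numerical checks.** The forward model is checked against the analytic
Radon transform of a uniform disk, $p(s) = 2\sqrt{r^2 - s^2}$ (the rim is
excluded from the comparison: the profile's derivative diverges there and a
discretised projector cannot track it at any fixed voxel size). The
reconstruction is checked by round trip (normalised cross-correlation with
the phantom inside the reconstruction circle ≥ 0.95 at 400 angles) and by a
convergence property (correlation does not decrease when the angle count
quadruples).

## The synthetic gut phantom

The phantom emulates a straight segment of terminal ileum in two channels.

**Autofluorescence.** Concentric layers at radii
`lumen < mucosa_outer < submucosa_outer < muscularis_outer`
(defaults 150/220/270/300 µm) with distinct intensities
(mucosa 0.9, submucosa 0.55, muscularis 0.75, lumen 0.02 on the internal
[0, 1] scale — chosen to give Otsu segmentation an unambiguous
tissue/background split while keeping the layers distinguishable). Villi are
radial bumps on the mucosal inner boundary:
$r_\text{in}(\varphi, z) = R_\text{lumen} - L_v\, a(\varphi)\, b(z)$, where
$a$ is a raised cosine in angle with frequency `villus_count_per_ring`,
clipped at 70% of its peak so each villus has a flat apex of finite width
(a knife-edge tip would be sub-voxel and unresolvable at realistic voxel
sizes), and $b$ is a squared raised cosine in $z$ with period
`villus_axial_period`. The product form puts one analytically known apex per
villus per ring — rings at $z = p/2 + jp$ — so the expected apex count is
exactly `rings × villi_per_ring`, which the density stage must recover.

**Marker.** Follicles are ellipsoids with a Gaussian radial profile
$I = I_\text{peak}\exp(-2m^2)$, where
$m^2 = (x/a)^2 + (y/b)^2 + (z/c)^2$ in the ellipsoid frame: the analytic
surface $m = 1$ sits at intensity $I_\text{peak} e^{-2} \approx 0.135\,
I_\text{peak}$, which is therefore the natural segmentation threshold when
testing volume recovery against the analytic $\tfrac{4}{3}\pi abc$. Cells
are single bright voxels placed uniformly at random in a named layer.
Default follicles sit on a 235 µm ring in the submucosa at 1/4, 1/2 and 3/4
of the sample length with volumes of roughly 1, 2 and 3.4 ×10⁶ µm³ — inside
the 1–5 ×10⁶ µm³ range where mature ILFs live.

**Noise.** Additive Gaussian noise (default σ = 0.01) with an optional
Poisson (shot-noise) mode; the modality itself does not prescribe a noise
model, so it is a documented choice. All randomness flows through
`rng_seed`; outputs are bit-identical across runs for a fixed spec.

**What the phantom does not emulate.** No optical point-spread function,
refraction, scattering or clearing-induced shrinkage; layer boundaries are
crisp; villi are idealised periodic bumps rather than fitted to measured
shape statistics; the tube is straight and the cross-section circular.
Passing tests therefore demonstrate that the *algorithms* recover known
geometry under realistic sampling and noise — not that any particular
biological sample will be segmented correctly with default thresholds,
which on real data remain user-set.

## Virtual unfolding

Per slice: Otsu threshold on the normalised slice, hole filling, largest
connected component, outer contour as the outline polygon, first-moment
centroid. The **seam** — where the tube is cut before unrolling — is the
outline vertex closest in angle to a ray cast from the centroid (default
45°). Angles are measured counterclockwise from the +x image axis with y
pointing down; this convention, and the counterclockwise traversal of the
outline, must be fixed somewhere for reproducible orientation of the
unfolded image, and both are fixed here and asserted by tests.

The outline is smoothed with a circular moving average (window 5 vertices)
before re-parameterisation: the raw contour of a digitised circle is a
staircase whose polyline length overestimates the true perimeter by up to
~10%, and smoothing brings the arc-length estimate within the 2% the tests
demand. The smoothed polygon is resampled at `step` (default one voxel)
starting at the seam, and the slice is sampled by bilinear interpolation
along inward normals from `band_outer` outside to `band_inner` inside the
outline, at voxel resolution. Rows of the straightened image run outermost
→ lumen; columns are arc length. Straightened slices are zero-padded to the
longest perimeter (seam-aligned at column 1) and the stack is transposed so
each layer of the unfolded volume is one radial depth.

Decisions and caveats:

* Seams are selected per slice independently (an optional cross-slice
  smoothing is deliberately *not* applied by default, mirroring per-section
  processing); for a straight tube the seam points are collinear within a
  pixel, which is tested.
* Normals that would cross the centroid are clamped at 98% of the centroid
  distance with a geometry warning, rather than folding through the centre.
* The unroll is not area-preserving: a layer at depth $d$ from an outline of
  radius $R$ oversamples by $\approx R/(R-d)$. Arc positions and counts are
  faithful; integrated intensities deep inside the band are not, so the
  mass-conservation test uses a thin band. Consequently, scales expressed in
  unfolded arc columns stretch by $R/(R-d)$ relative to physical lengths at
  the sampled radius — this matters when choosing detection scales below.
* Non-convex outlines are handled by the same normal construction but the
  45° seam ray may be ambiguous for strongly non-convex shapes; branched or
  torn cross-sections are out of scope.

## Villous density

Villus apexes are detected on one unfolded layer as local maxima of a
scale-normalised (zero-mean, positive-lobe-normalised) Laplacian-of-Gaussian
response, so `min_prominence` is in intensity units of the layer. Detections
require: response ≥ `min_prominence`, strict 8-neighbour local maximality
(plateau ties broken by lexicographic pixel order), and a greedy minimum
separation of about one villus width. Maxima are binned into square sectors
of `sector_size`; sector counts always partition the total, and each
sector's density is `count / sector_size²` (edge sectors keep the nominal
area — a documented simplification).

Parameter guidance, written in terms of the phantom defaults: detect on the
mid-villus layer (depth `muscularis_outer − (lumen_radius − villus_length/2)`,
where villus cross-sections are widest); because of the $R/(R-d)$ arc
stretch, a 40 µm-wide villus at 120 µm radius under a 300 µm outline appears
~100 µm wide in arc columns, so the defaults used in the tests are
`sigma_um = 30` and `min_separation_um = 90` with `min_prominence = 0.15`.
Recovery on the phantom is exact (60/60) noiselessly and stays within ±10%
at 10% amplitude noise across a neighbourhood of these settings; both are
recomputed by the acceptance script.

## Follicle segmentation and statistics

Gaussian smoothing at a fixed physical scale (default σ = 2 µm — small
relative to typical voxel sizes, it regularises surfaces without moving the
half-maximum boundary), absolute-intensity threshold (required parameter:
real thresholds are set by the user against their staining), 26-connected
component labelling (26- rather than 6-connectivity matches surface-based
object definitions for smoothed blobs), and a `min_voxels` filter that is
exact by construction — tested with objects straddling the cutoff. Volumes
are `voxel_count · voxel³`; on 1–5 ×10⁶ µm³ phantom follicles at 5 µm voxels
they recover within 10% (in practice well under 1%) with ordering preserved,
and the error shrinks as the voxel size decreases.

Spacing statistics are computed over **all pairs** (per follicle: min, mean,
max centroid-to-centroid distance). The natural alternative — axial
nearest-neighbour spacing — is provided as a mode, because "distance between
each follicle" is genuinely ambiguous; all-pairs is the default since it
degrades gracefully when follicles are not axially ordered. The mean of the
per-follicle minima is the mean nearest-neighbour spacing; on a phantom with
500 µm regular spacing it recovers 500 µm within one voxel.

Cell density is `cells inside mask / mask area`, with the OPT visibility
rule `density ≥ threshold` (default 400 cells/mm², inclusive — the boundary
case counts as visible, and the threshold is configurable because it is an
empirical, approximate figure).

## Reverse-OPT bookkeeping

Sections are half-open intervals $[kt, (k+1)t)$, zero-based from the cutting
face at the configured origin end; half-open intervals partition the axis so
no section is double-assigned. A ROI's axial extent from 1-based slices
$i..j$ is $((i-1)\,v,\; j\,v)$, mirrored when the origin is distal so that
proximal and distal extents of the same ROI always sum to the sample length
— that invariant, rather than any worked example, defines the mirror
arithmetic. No shrinkage/rehydration scale factor is applied between OPT
space and section space by default; distances are measured along the
straight grid axis, so curved samples are the user's responsibility to mount
straight. Index arithmetic is exact integer arithmetic and is tested against
a brute-force interval-intersection oracle.

## Pipeline, IO and determinism

`run_pipeline()` chains phantom → simulate → reconstruct → unfold → quantify
→ revopt with a nested key-value configuration (unknown keys rejected before
any work), per-stage `enabled` toggles, TIFF/CSV artifacts and a JSON report
with stage timings, counts, parameters and the seed; a fixed seed makes the
whole run reproducible. Volumes are 16-bit multi-page TIFFs (one page per
slice; intensities live on [0, 1] internally) with JSON sidecars carrying
voxel size and channel, so write→read round trips are bit-identical for
16-bit data. CSV columns embed their units (e.g. `volume_um3`).

## Problem sizes used in the checks

The shipped tests and the acceptance script run at deliberately modest
sizes, chosen so the full suite completes in about a minute while every
recovery result is non-trivial: 128×128×32 disks at 400 angles for the FBP
round trip; a 256×256 annulus at 1 µm voxels for unfolding geometry; an
80×80×80 villous phantom (60 apexes) at 10 µm voxels; 480×96×96 marker
volumes at 5 µm voxels for follicle volumes and spacing; and a 128×64×64
end-to-end run at 400 angles. The algorithms contain nothing size-specific;
larger volumes cost proportionally more time and memory.

## Known limitations

* Parallel-beam only; no cone-beam, telecentricity or focal-plane
  deconvolution modelling, and no stitching of sequential segments.
* The simulator does not attempt to reproduce any particular instrument's
  spatial resolution; resolution-dependent conclusions need real
  calibration data.
* Unfolding assumes one simply connected cross-section per slice.
* Statistical group comparisons on exported tables are left to standard
  tools; the package stops at the per-sample measurements.
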