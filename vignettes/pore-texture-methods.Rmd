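---
title: "Pore texture analysis for implanted lightweight mesh identification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore texture analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretex)
```

## The problem

Lightweight (LW) polypropylene hernia meshes are thin, large-pore implants
that CT and MRI cannot visualize. In conventional 2D ultrasound sectional
views (axial/sagittal), both an implanted LW mesh and the abdominal-wall
fascia render as a thin linear hyperechoic band, so they are easily
confused. Automated 3D ultrasound (ABUS-style) volumes add the coronal
plane — the plane parallel to the skin — where the mesh's periodic pore
lattice becomes visible as a texture that fascia does not have.

`poretex` implements the quantitative side of that observation: per-ROI
texture features (2D and 3D gray-level co-occurrence statistics, spectral
fractal dimension), two positional features, and a per-feature inter-class
separability ranking that quantifies which features distinguish mesh from
fascia. Because no clinical ABUS dataset of implanted meshes is publicly
deposited, the package ships a first-class synthetic phantom generator that
emulates the imaging situation; all quantitative claims in this vignette
are computed by the package's tests and acceptance script, not imported
from elsewhere.

## Data model and coordinate conventions

A volume is a 3D array with axes fixed as (z = depth below the probe,
x = transducer width, y = mechanical sweep), with per-axis voxel spacing in
mm. The coronal plane is x–y at fixed z; the axial plane is the
conventional B-mode frame. Indices in the geometry API are 0-based with
half-open ranges; voxel *i* covers `[i*s, (i+1)*s)` mm so its center is at
`(i + 0.5)*s`.

The canonical region of interest is a 10 mm cube. At the clinical
resolution of 0.07 mm in-plane and 0.53 mm sweep spacing this is
143 × 143 × 19 voxels; voxel counts come from round-half-up of
`size_mm / spacing` (143 = round(142.86), 19 = round(18.87)). ROIs that
would exceed the volume raise an error — there is no silent clipping.

Gray-level quantization is uniform min–max binning of the region's own
intensity range into `G` levels 0 … G−1 (default G = 32, a config knob).
Quantization is per region, not global across samples: published descriptions of this
pipeline do not state a normalization, per-region binning makes features
invariant to per-patient gain, and the alternative is exposed through the
pipeline configuration rather than hard-wired. A constant region maps to
level 0 so degenerate inputs flow through the feature code, which has its
own documented degenerate-case behavior (below).

Volumes are read and written as single-file NIfTI-1 (`.nii`/`.nii.gz`)
with spacing in `pixdim`, plus an optional JSON sidecar
`{"spacing_mm": [z, x, y], "axes": "zxy"}` for containers written without
physical metadata. The reader/writer is a minimal base-R implementation
because no NIfTI package is available in the target environment; it
handles the common scalar dtypes, gzip, byte order, and scl slopes, and
rejects multi-frame (non-grayscale) input.

## 2D co-occurrence features

The gray-level co-occurrence matrix (GLCM) for displacement D counts pairs
of pixels a vector D apart. Four independent directions (0°, 45°, 90°,
135°) at distance d = 1 cover the 8-neighborhood once pairs are
accumulated symmetrically (each ordered pair and its reverse), which also
makes P symmetric. Twelve scalar features are computed from the normalized
matrix — energy, contrast, correlation, variance, homogeneity, sum
average, entropy, autocorrelation, dissimilarity, cluster shade, cluster
prominence, maximum probability — and averaged over the four directions
into a single 12-vector.

Resolved ambiguities, recorded here because the printed formulas in this
literature are not fully self-consistent:

* The marginal "standard deviations" are printed as second central
  moments; the correlation denominator divides by σ·σ, so we take square
  roots of the printed quantities (the classical Haralick definition).
* The entropy logarithm is natural; `0·log 0 ≡ 0`.
* The variance feature's μ is the row-marginal mean μx (= μy by
  symmetry).
* Gray levels are 0-based, matching the quantizer. Features that depend
  on the index origin (sum average, autocorrelation) are therefore defined
  on 0 … G−1.
* A constant region has zero marginal variance; correlation is defined as
  0 by convention so degenerate phantoms still yield finite vectors.

All twelve features are verified against an independent brute-force
pair-enumeration oracle to 1e-12 relative tolerance on randomized small
regions (up to 8×8, G ≤ 4).

## 3D (volumetric) co-occurrence features

The volumetric extension uses 13 symmetry-independent unit offsets whose
± closure is the 26-neighborhood. The G × G × G table P(i, j, k) is read
as *collinear-triplet* co-occurrence: for a voxel v and offset D, the
triplet (v, v+D, v+2D) contributes its level triple, plus the reversed
triple — the only interpretation under which a three-index table is
well-defined; pair-based variants cannot populate G³ cells. Reversal
accumulation gives the symmetry P(i,j,k) = P(k,j,i). Offsets are in voxel
units on the native anisotropic grid (no spacing correction), exactly as
the method prescribes d = 1 voxel per axis. Forward triplets rather than
centered ones are scanned; the two differ only in boundary counts.

The twelve 3D features mirror the 2D set with these documented decisions:

* contrast and homogeneity use the symmetric pairwise term
  (i−j)² + (i−k)² + (j−k)² (repairing an obvious bracket typo in the
  printed homogeneity formula);
* the 3D "variance" is implemented as printed in the literature, as
  Σ(P − m)² over table entries with m the mean entry 1/G³ — which makes
  it an affine function of energy (f4 = f1 − 1/G³). This differs
  structurally from the 2D variance; we follow the print and note it;
* the 3D sum average uses a genuine triplet sum marginal
  P(s) = Σ_{i+j+k=s} P(i,j,k), s ∈ [0, 3(G−1)], since the printed formula
  recycles the 2D symbol verbatim;
* correlation is the third cross central moment over the product of the
  three marginal standard deviations, 0 for a zero-variance table.

Features are averaged over the 13 directions. Everything is verified
against an independent exhaustive triplet-enumeration oracle (regions up
to 5×5×5, G ≤ 3, 1e-12 relative).

## Spectral fractal dimension

Texture roughness is estimated from the slope of the radially averaged FFT
power spectrum. The region is mean-subtracted (a DC term would destroy the
log–log fit; published formulations are silent here, but the choice is forced),
transformed with the FFT, and P = |F|² is put on a zero-centered frequency
grid in cycles/mm computed per axis from the voxel spacing — so the radial
frequency is physically meaningful on the anisotropic grid (pass spacing 1
for voxel-unit frequencies). No window is applied by default (none is
specified by the method); a Hann option exists for leakage control.

The spectrum is point-sampled by multilinear interpolation at 30 uniformly
spaced radii per direction — from the lowest nonzero radial bin to the
common (minimum per-axis) Nyquist radius — along 24 directions in 2D and
24 azimuth × 12 zenith directions in 3D, then averaged over directions at
each radius. Ordinary least squares of log P_f on log f gives the slope;
with the convention P ∝ f^(−β), β is the negative slope and

FD = (3·D_T + 2 − β) / 2 = (8 − β)/2 in 2D, (11 − β)/2 in 3D.

Degenerate inputs (constant region → all-zero spectrum) raise a
degenerate-spectrum error which the pipeline converts to an `NA` feature
with a diagnostic. The estimator is validated end-to-end on constructed
random-phase power-law fields: β ∈ {1.5, 2.5, 3.5} is recovered within
±0.15 at 256² (2D) and ±0.25 at 64³ (3D); in practice the error is
under 0.05.

Within the pipeline, the 2D FD is computed on the central coronal slice —
the plane where pore texture lives — and the 3D FD on the full ROI; the
slice policy is configurable.

## Positional features

Neither positional feature is given as a formula in the source; both are
reconstructions of prose descriptions, documented as such:

* **f39 (scan depth)** — the ROI centroid depth in mm below the probe
  face: `(centroid index + 0.5) × depth spacing`. Implanted meshes sit at
  1–3 cm depth, but so does fascia, so this feature is expected to be a
  weak discriminator.
* **f40 (sac proximity)** — the coronal-plane Euclidean distance between
  the ROI centroid and the annotated hernia-sac centroid, normalized by
  the coronal field-of-view diagonal (dimensionless, in [0, 1]). Recurrent
  hernias form where mesh was implanted, so proximity to the sac predicts
  mesh. A missing annotation yields `NA`, and such samples are excluded
  from that feature's ranking input only.

## Inter-class distance ranking

Features are pooled (both classes) z-score normalized; zero-variance
columns map to zeros with a warning, and min–max normalization is
available as a config alternative. For each feature,

d(C_i, C_j) = |m_i − m_j| − s(C_i) − s(C_j)

with m the class mean and s the class *sample* standard deviation (n−1) —
the simplest scalar scatter consistent with the formula's dimensional
form, which published formulations leave undefined. Distances can be negative
(overlapping classes) and are reported as such; they still order features.
Features are ranked descending with ties broken by canonical column order,
and the top k = 25 are selected by default. Normalization happens before
the class statistics, following the order of operations in the method's
description; ranking is invariant to any per-feature affine transform.

## The synthetic phantom world

The generator emulates what the analysis assumes about ABUS imaging of the
repaired abdominal wall. Its defaults are the package's statement of that
world; they were designed from imaging physics and the method's own
qualitative descriptions, then frozen. Components:

* **Speckle.** I.i.d. Rayleigh envelope amplitudes (the fully developed
  speckle model), smoothed by a separable Gaussian point-spread blur of
  σ = (0.1, 0.2, 0.4) mm in (depth, width, sweep) — axial, lateral, and
  elevational resolution scales of an ~11 MHz linear probe. The blur is a
  circular FFT convolution with unit DC gain, so the Rayleigh mean
  s·√(π/2) is preserved exactly (tested to 3 standard errors).
* **Fascia.** A band with Gaussian depth profile (default thickness
  ~1 mm), multiplicative gain peaking at `echogenicity` (default 3) —
  echogenic tissue keeps its full speckle, so gain is multiplicative, not
  additive — modulated along the band by a smooth random "fibrous
  patchiness" field (30 random cosines, correlation length 3.5 mm,
  relative amplitude 0.45): real fascia is inhomogeneous, not a uniform
  bright sheet. The patch field is nonperiodic by construction.
* **Mesh.** A square pore lattice (period = pore size × shrink factor,
  default pore 3 mm — a typical LW mesh — and filament width 0.5 mm) on a
  surface that can be rotated in plane, tilted out of the coronal plane,
  and sagged on a sphere (curvature), mirroring the four in-vitro fragment
  gestures: flat, rotated, tilted, curled. Shrinkage contracts the
  lattice period.
* **Scene composition in the labeled dataset.** Mesh lies against and
  overlaps the fascia: each mesh sample embeds the lattice *into* a
  patchy fascia lamella at the same depth (voxelwise amplitude saturation
  of the two gain fields, filaments protruding 1.3× above the lamella
  peak), with a second interface band 1.2–2.2 mm above; fascia samples
  get the same lamella and second band without the lattice. Sectional
  views of both classes therefore show the same layered linear
  hyperechoic appearance — only the spatial *organization* in the coronal
  plane differs. Rendered intensities are B-mode log-compressed
  (`log10(1 + 10·envelope)`), since scanner display images, not raw
  envelopes, are what gets analyzed.
* **Per-sample variation.** Sheet depth uniform in 10–30 mm (the 1–3 cm
  placement range); mesh tilt U[0, 25]°, curvature radius U[20, 80] mm,
  linear shrink U[0.9, 1] (clinical 10–20% linear shrinkage), in-plane
  rotation U[0, 90)°; fascia tilt U[0, 5]° (fascia lies parallel to the
  skin under a flat probe); lamella thickness U[0.6, 1.0] mm; per-sample
  echogenicity U[0.7, 1.3] × 3 (patient and gain variability); ROI depth
  centering error U[−0.8, 0.8] mm (manual segmentation is imperfect).
* **Sac annotations.** Planted near mesh ROIs (Gaussian, σ = 3 mm) and
  uniformly over the coronal field for fascia samples, injecting the
  proximity structure that makes f40 discriminative by construction.

What the generator does *not* emulate: attenuation and time-gain
compensation, refraction/reverberation artifacts, posterior acoustic
shadowing (a heavyweight/composite-mesh sign, identified visually rather
than by this pipeline), hexagonal knit geometry, scan conversion, or any
real tissue heterogeneity beyond the band/patch model. A green benchmark
test therefore establishes that the *pipeline* ranks feature families as
expected in this stated world — not that it would do so on clinical data.

### The benchmark and what it shows

The default benchmark (`benchmark_dataset()`) renders 30 mesh + 30 fascia
phantoms at half the clinical in-plane resolution (0.14 mm; sweep
unchanged) — a deliberate compute scale-down that preserves pore and
filament geometry in voxels — extracts all 40 features per sample, and
ranks them. At the default seed the acceptance suite asserts the
qualitative structure the method reports: the 3D GLCM group's mean
inter-class distance exceeds the 2D coronal group's, which exceeds the 2D
axial group's; the 3D FD feature attains the maximum distance of all 40;
and the sac-proximity feature beats the scan-depth feature. The group
ordering and the f40 > f39 ordering are stable across every seed we
tried; the "3D FD is the single maximum" property is real but fragile at
n = 30 + 30 (at some seeds it ranks among the top dozen rather than
first), which is the expected behavior of a stochastic extreme-value
statement at this sample size. In this world most per-feature distances
are *negative* — within-class scatter exceeds the mean gap — which is
itself informative: single features do not separate the classes cleanly;
the ordering of feature families is what carries the signal.

## Numerical and degenerate-input policy

* Quantization of a constant region → all level 0; co-occurrence features
  then take their analytic degenerate values (energy = max probability =
  1, contrast = entropy = 0, correlation = 0 by convention).
* Regions smaller than a displacement/triplet raise degenerate-input
  errors; the pipeline excludes such samples with a logged reason and
  fails loudly if more than half the samples are excluded.
* Constant regions cannot support a spectrum: the FD stage yields `NA`
  plus a diagnostic instead of aborting the sample.
* All randomness is seed-derived; identical seed and configuration give
  byte-identical `features.csv` and `ranking.json` (tested).
* Ranking ties are broken by canonical column order, so results are
  reproducible even with duplicated features.

## Known limitations

* The 3D f4 follows its printed (energy-affine) form; users wanting a
  2D-consistent variance should compute it from the table directly.
* The spectral FD fit range is tied to the grid (first nonzero bin to the
  common Nyquist); with 19 sweep slices the 3D radial range is short, and
  fit r² diagnostics are exported for exactly this reason.
* f39/f40 are reconstructions of prose, not published formulas; their
  definitions are the simplest consistent ones and are isolated in one
  module.
* The phantom world is a model. Its parameters are honest but not fitted
  to clinical data — no claim of clinical contrast calibration is made.
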