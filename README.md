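# poretex

Pore-texture analysis of automated 3D ultrasound (ABUS-style) volumes for
identifying implanted lightweight (LW) surgical hernia mesh.

## The problem

LW polypropylene meshes are thin, large-pore implants used in most
abdominal-wall hernia repairs. They are invisible to CT and MRI, and in
conventional 2D ultrasound sectional views both the mesh and the
abdominal-wall fascia render as a thin linear hyperechoic band — easily
confused. 3D ultrasound adds the *coronal* plane (parallel to the skin),
where the mesh's periodic pore lattice appears as a texture that fascia
lacks. `poretex` turns that observation into numbers: it extracts 40
texture/positional features per region of interest and ranks them by how
well they separate mesh from fascia.

For radiologists' collaborators, medical-imaging researchers and
methodologists who want a reproducible, fully tested reference
implementation of this pipeline — including a synthetic phantom world to
run it on, since no clinical ABUS mesh dataset is publicly deposited.

## What it computes

Per 10 mm ROI (143 × 143 × 19 voxels at the clinical 0.07 mm in-plane /
0.53 mm sweep resolution):

* **2D GLCM features** (12 per plane, axial and coronal): gray-level
  co-occurrence statistics *f1..f12* (energy, contrast, correlation,
  variance, homogeneity, sum average, entropy, autocorrelation,
  dissimilarity, cluster shade, cluster prominence, maximum probability),
  averaged over the 4 directions of the 8-neighborhood at distance d = 1.
* **3D GLCM features** (12): the volumetric extension over collinear
  voxel triplets (v, v+D, v+2D) along the 13 independent directions of
  the 26-neighborhood, P(i,j,k) normalized with reversal symmetry.
* **Spectral fractal dimension** (2D and 3D): least-squares slope β of
  log P_f vs log f on the radially averaged FFT power spectrum (24
  directions × 30 radii in 2D; 24 azimuth × 12 zenith × 30 in 3D), with
  FD = (3·D_T + 2 − β)/2, i.e. (8 − β)/2 in 2D and (11 − β)/2 in 3D.
* **Positional features**: f39 = ROI centroid scan depth (mm);
  f40 = coronal-plane distance to the annotated hernia sac, normalized by
  the field-of-view diagonal.
* **Feature ranking**: pooled z-score normalization, then per-feature
  inter-class distance d(C_i, C_j) = |m_i − m_j| − s(C_i) − s(C_j)
  (class means and sample standard deviations), sorted descending, top
  k = 25 selected.

See `vignettes/pore-texture-methods.Rmd` for the formulas, the resolved
print ambiguities, and the design rationale of the synthetic world.

## Worked example

Simulate a small labeled mesh/fascia dataset, extract all 40 features per
sample, and rank them:

```r
library(poretex)

ds <- generate_labeled_dataset(6, 6, seed = 1,
  base_spec = phantom_spec(shape_mm = c(40, 14, 14),
                           spacing_mm = c(0.14, 0.14, 0.53)))
res <- run_pipeline(ds$samples, ds$volumes, config = pipeline_config(k = 10))

res$group_summary
#>        group mean_distance
#> 1    axial2d    -0.8104612
#> 2  coronal2d    -1.0256488
#> 3     glcm3d    -0.1670560
#> 4         fd    -1.3075175
#> 5 positional    -1.3010597

head(res$ranking$table[order(res$ranking$table$rank),
                       c("feature", "distance", "rank")], 5)
#>  feature  distance rank
#>    v3_f8 0.5416581    1
#>   v3_f11 0.3986300    2
#>   v3_f10 0.3836683    3
#>    v3_f6 0.2140256    4
#>   cor_f2 0.0953865    5
```

The group summary is the package's small-scale analogue of the clinical
question: the 3D GLCM group separates mesh from fascia best
(mean inter-class distance −0.17), the single-slice coronal features are
weaker, and the axial-plane features weaker still — most distances are
negative because each class's scatter exceeds the mean gap for a single
feature, which is exactly why feature *ranking* (not any one feature) is
the object of interest. At the full benchmark size (30 + 30 phantoms,
`benchmark_dataset()`), the 3D FD feature attains the maximum distance of
all 40.

Single-volume inspection works at any level of the API:

```r
v <- ds$volumes[["mesh_001"]]$volume
v
#> <us_volume> 286 x 100 x 26 voxels (z depth, x width, y sweep)
#>   spacing  0.14 x 0.14 x 0.53 mm
#>   extent   40 x 14 x 13.8 mm
roi <- extract_roi(v, c(ds$samples$cz_mm[1], 7, 7), c(10, 10, 10))
spectral_fd(roi)
#> <fd_result> 3D: beta = 3.2275, FD = 3.8862 (r2 = 0.995)
```

A mesh ROI's 3D FD (here 3.89) sits well above a fascia ROI's (typically
~3.5 in this world): the pore lattice adds mid-frequency spectral power,
flattening the radial spectrum.

## Command line

```sh
Rscript inst/cli/poretex.R simulate --config cfg.json --out data/
Rscript inst/cli/poretex.R extract  --rois data/rois.csv --out results/
Rscript inst/cli/poretex.R rank     --features results/features.csv --k 25 \
                                    --out results/ranking.json
```

`cfg.json` keys mirror `phantom_spec()` (under `"phantom"`) and
`pipeline_config()` (under `"pipeline"`). Outputs: `features.csv`
(canonical 40-column layout), `ranking.json` (per-feature class means,
scatters, distance, rank, selected flag), `report.md` (group summaries
and the top-k list).

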