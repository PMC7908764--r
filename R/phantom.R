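# Seeded synthetic phantoms: Rayleigh speckle background, a lightweight-mesh
# sheet as a periodic pore lattice on a (possibly rotated / tilted / curved /
# shrunk) surface, and a fascia sheet as a smooth hyperechoic band.
#
# The speckle model is the standard B-mode amplitude model: i.i.d. Rayleigh
# envelope smoothed by a small Gaussian point-spread blur (applied as a
# circular FFT convolution, which preserves the sample mean exactly). The
# mesh is a square lattice (period = pore size; shrinkage contracts the
# period) of filaments with an echogenicity gain over background. The four
# canonical spatial variations seen in vitro -- flat, rotated in plane,
# tilted in depth, curved/shrunk -- map onto the transform parameters.

#' Phantom specification
#'
#' Collects every knob of the synthetic scene. Defaults state the imaging
#' world the analysis assumes: 0.07 mm in-plane / 0.53 mm sweep voxels, a
#' 3 mm pore lattice of 0.5 mm filaments (a typical lightweight
#' polypropylene mesh) at 20 mm depth, Rayleigh speckle of unit scale.
#'
#' @param shape_mm volume extent in mm (depth, width, sweep).
#' @param spacing_mm voxel sizes in mm (depth, width, sweep).
#' @param scene one of `"background"`, `"mesh"`, `"fascia"`.
#' @param pore_size_mm lattice period of the unshrunk mesh (default 3).
#' @param filament_width_mm filament thickness (default 0.5); must be
#'   smaller than `pore_size_mm`.
#' @param depth_mm sheet placement depth below the probe face.
#' @param sheet_size_mm side length of the (square) sheet; default spans
#'   the volume's larger coronal extent.
#' @param rotation_deg in-plane (coronal) lattice rotation.
#' @param tilt_deg rotation of the sheet out of the coronal plane, about
#'   the width axis.
#' @param curvature_radius_mm radius of the spherical sag applied to the
#'   sheet; `Inf` (default) = flat.
#' @param shrink_factor multiplies the lattice period, in (0, 1]; 0.5
#'   halves the period (post-implantation shrinkage).
#' @param fascia_thickness_mm thickness of the fascia band (default 1).
#' @param fascia_patchiness relative amplitude of the smooth random gain
#'   modulation along the fascia band (default 0.45): real fascia is
#'   fibrous and inhomogeneous, not a uniform bright sheet. 0 disables.
#' @param patch_corr_mm correlation length of the patch modulation
#'   (default 3.5 mm).
#' @param echogenicity intensity gain of filament/fascia voxels over the
#'   background, in units of the speckle scale (default 3).
#' @param speckle_scale Rayleigh scale parameter (default 1).
#' @param blur_sigma_mm Gaussian point-spread sigma per axis in mm
#'   (depth, width, sweep); default `c(0.1, 0.2, 0.4)` emulates axial,
#'   lateral and elevational resolution at ~11 MHz.
#' @param seed RNG seed (default 1).
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape_mm = c(40, 14, 14),
                         spacing_mm = c(0.07, 0.07, 0.53),
                         scene = c("background", "mesh", "fascia"),
                         pore_size_mm = 3,
                         filament_width_mm = 0.5,
                         depth_mm = 20,
                         sheet_size_mm = NULL,
                         rotation_deg = 0,
                         tilt_deg = 0,
                         curvature_radius_mm = Inf,
                         shrink_factor = 1,
                         fascia_thickness_mm = 1,
                         fascia_patchiness = 0.45,
                         patch_corr_mm = 3.5,
                         echogenicity = 3,
                         speckle_scale = 1,
                         blur_sigma_mm = c(0.1, 0.2, 0.4),
                         seed = 1L) {
  scene <- match.arg(scene)
  shape_mm <- as.numeric(shape_mm); spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(shape_mm) == 3L, length(spacing_mm) == 3L,
            all(shape_mm > 0), all(spacing_mm > 0))
  if (!(pore_size_mm > filament_width_mm && filament_width_mm > 0))
    stop("need pore_size_mm > filament_width_mm > 0", call. = FALSE)
  if (depth_mm < 0 || depth_mm > shape_mm[1])
    stop("depth_mm must lie within the volume", call. = FALSE)
  if (!(shrink_factor > 0 && shrink_factor <= 1))
    stop("shrink_factor must be in (0, 1]", call. = FALSE)
  if (speckle_scale <= 0)
    stop("speckle_scale must be positive", call. = FALSE)
  if (is.null(sheet_size_mm)) sheet_size_mm <- max(shape_mm[2:3])
  structure(list(
    shape_mm = shape_mm, spacing_mm = spacing_mm, scene = scene,
    pore_size_mm = pore_size_mm, filament_width_mm = filament_width_mm,
    depth_mm = depth_mm, sheet_size_mm = sheet_size_mm,
    rotation_deg = rotation_deg, tilt_deg = tilt_deg,
    curvature_radius_mm = curvature_radius_mm,
    shrink_factor = shrink_factor,
    fascia_thickness_mm = fascia_thickness_mm,
    fascia_patchiness = fascia_patchiness, patch_corr_mm = patch_corr_mm,
    echogenicity = echogenicity, speckle_scale = speckle_scale,
    blur_sigma_mm = rep_len(as.numeric(blur_sigma_mm), 3L),
    seed = as.integer(seed)), class = "phantom_spec")
}

# separable Gaussian blur via circular FFT convolution; sigma in voxels may
# be 0 (no blur on that axis). H(0) = 1, so the sample mean is preserved.
.gauss_blur_fft <- function(x, sigma_vox) {
  d <- dim(x)
  if (all(sigma_vox <= 0)) return(x)
  X <- stats::fft(x)
  for (ax in seq_along(d)) {
    if (sigma_vox[ax] <= 0) next
    n <- d[ax]
    f <- ifelse(seq_len(n) - 1 <= n %/% 2, seq_len(n) - 1,
                seq_len(n) - 1 - n) / n
    h <- exp(-2 * pi^2 * sigma_vox[ax]^2 * f^2)
    X <- sweep(X, ax, h, `*`)
  }
  Re(stats::fft(X, inverse = TRUE)) / prod(d)
}

#' Generate a speckle background volume
#'
#' Voxels are i.i.d. Rayleigh(`speckle_scale`) envelope amplitudes,
#' smoothed by the spec's Gaussian point-spread blur. Deterministic under
#' `spec$seed`.
#'
#' @param spec a `phantom_spec`.
#' @return a `us_volume`.
#' @export
make_speckle_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- pmax(2L, as.integer(round_half_up(spec$shape_mm / spec$spacing_mm)))
  set.seed(spec$seed)
  u <- stats::runif(prod(dims))
  x <- array(spec$speckle_scale * sqrt(-2 * log(u)), dim = dims)
  x <- .gauss_blur_fft(x, spec$blur_sigma_mm / spec$spacing_mm)
  x[x < 0] <- 0
  ultrasound_volume(x, spec$spacing_mm)
}

# voxel-center coordinate grids (mm) as three vectors
.vox_centers <- function(volume) {
  d <- dim(volume$data)
  Map(function(n, s) (seq_len(n) - 0.5) * s, d, as.list(volume$spacing))
}

# local sheet-frame coordinates for every voxel: in-plane rotation about z
# by `rot`, then tilt about the width (x) axis by `tilt`, sheet centered at
# (depth, center of the coronal plane). Returns lx, ly (in-sheet) and lz
# (normal offset) as 3D arrays.
.sheet_frame <- function(volume, depth_mm, rotation_deg, tilt_deg) {
  cg <- .vox_centers(volume)
  d <- dim(volume$data)
  ext <- volume_extent_mm(volume)
  z <- array(rep(cg[[1]], times = d[2] * d[3]), dim = d) - depth_mm
  x <- array(rep(rep(cg[[2]], each = d[1]), times = d[3]), dim = d) -
    ext[2] / 2
  y <- array(rep(cg[[3]], each = d[1] * d[2]), dim = d) - ext[3] / 2
  a <- rotation_deg * pi / 180
  t <- tilt_deg * pi / 180
  # inverse in-plane rotation of the coronal coordinates
  xr <- cos(a) * x + sin(a) * y
  yr <- -sin(a) * x + cos(a) * y
  # inverse tilt about the x axis mixes yr and depth offset z
  ly <- cos(t) * yr + sin(t) * z
  lz <- -sin(t) * yr + cos(t) * z
  list(lx = xr, ly = ly, lz = lz)
}

# corner depth check: does the transformed square sheet stay inside the
# volume's depth range? corners in local coords, mapped forward.
.sheet_fits <- function(volume, spec) {
  half <- spec$sheet_size_mm / 2
  corners <- expand.grid(lx = c(-half, 0, half), ly = c(-half, 0, half))
  sag <- if (is.finite(spec$curvature_radius_mm))
    (corners$lx^2 + corners$ly^2) / (2 * spec$curvature_radius_mm) else 0
  t <- spec$tilt_deg * pi / 180
  # forward map of local (ly, lz = -sag) to a depth offset
  z_off <- sin(t) * corners$ly + cos(t) * (-sag)
  z_abs <- spec$depth_mm + z_off
  all(z_abs >= 0 & z_abs <= volume_extent_mm(volume)[1])
}

#' Embed a lightweight-mesh sheet into a volume
#'
#' Adds a square pore lattice of period
#' `pore_size_mm * shrink_factor` lying on a surface at `depth_mm`,
#' optionally rotated in plane, tilted out of the coronal plane and sagged
#' on a sphere of radius `curvature_radius_mm`. Filament voxels are
#' multiplied by the `echogenicity` gain (echogenic structures keep their
#' full speckle) and marked in `mesh_mask`.
#'
#' @param volume a `us_volume` (typically from [make_speckle_volume()]).
#' @param spec a `phantom_spec`.
#' @return A `phantom_result`: list with `volume`, `mesh_mask`,
#'   `fascia_mask`, `sac_center_mm` (NULL here).
#' @export
add_mesh_sheet <- function(volume, spec) {
  stopifnot(inherits(volume, "us_volume"), inherits(spec, "phantom_spec"))
  if (!.sheet_fits(volume, spec))
    stop("transformed mesh sheet exits the volume", call. = FALSE)
  fr <- .sheet_frame(volume, spec$depth_mm, spec$rotation_deg, spec$tilt_deg)
  sag <- if (is.finite(spec$curvature_radius_mm))
    (fr$lx^2 + fr$ly^2) / (2 * spec$curvature_radius_mm) else 0
  lz <- fr$lz + sag
  period <- spec$pore_size_mm * spec$shrink_factor
  w <- spec$filament_width_mm
  on_lattice <- ((fr$lx + w / 2) %% period < w) |
                ((fr$ly + w / 2) %% period < w)
  half <- spec$sheet_size_mm / 2
  in_sheet <- abs(fr$lx) <= half & abs(fr$ly) <= half
  mask <- abs(lz) <= w / 2 & on_lattice & in_sheet
  # multiplicative gain: echogenic structures speckle proportionally
  data <- volume$data
  data[mask] <- data[mask] * spec$echogenicity
  structure(list(volume = ultrasound_volume(data, volume$spacing),
                 mesh_mask = mask,
                 fascia_mask = array(FALSE, dim = dim(data)),
                 sac_center_mm = NULL),
            class = "phantom_result")
}

#' Embed a fascia sheet into a volume
#'
#' Adds a smooth continuous hyperechoic band of thickness
#' `fascia_thickness_mm` at `depth_mm` (tilt respected, no periodic
#' structure): intensities are multiplied by a Gaussian depth profile
#' peaking at the `echogenicity` gain. Band voxels are marked in
#' `fascia_mask`.
#'
#' @inheritParams add_mesh_sheet
#' @return a `phantom_result` with `fascia_mask` set.
#' @export
add_fascia_sheet <- function(volume, spec) {
  stopifnot(inherits(volume, "us_volume"), inherits(spec, "phantom_spec"))
  if (!.sheet_fits(volume, spec))
    stop("transformed fascia sheet exits the volume", call. = FALSE)
  fr <- .sheet_frame(volume, spec$depth_mm, 0, spec$tilt_deg)
  th <- spec$fascia_thickness_mm
  half <- spec$sheet_size_mm / 2
  in_sheet <- abs(fr$lx) <= half & abs(fr$ly) <= half
  profile <- exp(-fr$lz^2 / (2 * (th / 2.355)^2)) * in_sheet
  mask <- abs(fr$lz) <= th / 2 & in_sheet
  # smooth random gain modulation along the band: fascia is fibrous and
  # patchy, not uniformly bright -- a random field with ~patch_corr_mm
  # correlation length, nonperiodic by construction
  if (spec$fascia_patchiness > 0) {
    set.seed(spec$seed + 7919L + as.integer(round(spec$depth_mm * 97)))
    K <- 30L
    fmax <- 1 / spec$patch_corr_mm
    fr_k <- stats::runif(K, 0.15 * fmax, fmax)
    az_k <- stats::runif(K, 0, 2 * pi)
    ph_k <- stats::runif(K, 0, 2 * pi)
    S <- 0
    for (k in seq_len(K))
      S <- S + cos(2 * pi * fr_k[k] *
                     (cos(az_k[k]) * fr$lx + sin(az_k[k]) * fr$ly) + ph_k[k])
    S <- S * sqrt(2 / K)
    patch <- pmax(0, 1 + spec$fascia_patchiness * S)
    profile <- profile * patch
  }
  data <- volume$data * (1 + (spec$echogenicity - 1) * profile)
  structure(list(volume = ultrasound_volume(data, volume$spacing),
                 mesh_mask = array(FALSE, dim = dim(data)),
                 fascia_mask = mask,
                 sac_center_mm = NULL),
            class = "phantom_result")
}

#' Generate a labeled synthetic mesh/fascia dataset
#'
#' Draws `n_mesh` mesh and `n_fascia` fascia phantoms with randomized
#' placement: sheet depth uniform in 10--30 mm (the 1--3 cm scan depth at
#' which tension-free meshes sit), random in-plane rotation, mild tilt,
#' curvature and shrinkage for mesh sheets, variable thickness for fascia.
#' Each sample gets one ROI centered on its sheet and a synthetic
#' hernia-sac annotation: near the ROI for mesh samples (recurrent hernias
#' form where mesh was implanted, so proximity to the sac predicts mesh),
#' uniform over the coronal field for fascia samples.
#'
#' @param n_mesh,n_fascia sample counts per class (each >= 1).
#' @param seed master RNG seed; every phantom derives its own sub-seed.
#' @param base_spec a `phantom_spec` carrying geometry/speckle defaults;
#'   its `depth_mm` and transform fields are overridden per sample.
#' @param out_dir if non-NULL, volumes are written there as NIfTI plus a
#'   `rois.csv` and `provenance.json`.
#' @param render if `FALSE`, only the sample table is produced (no volume
#'   rasterization) -- useful for bookkeeping at the full cohort size.
#' @param roi_size_mm ROI physical size (default 10 mm cube).
#' @return list with `samples` (data.frame: sample_id, volume_path, cz_mm,
#'   cx_mm, cy_mm, label, sac_cx_mm, sac_cy_mm), `volumes` (named list of
#'   `phantom_result`, or NULL when `render = FALSE` and `out_dir` is
#'   NULL), `seed`.
#' @export
generate_labeled_dataset <- function(n_mesh, n_fascia, seed = 1L,
                                     base_spec = phantom_spec(),
                                     out_dir = NULL, render = TRUE,
                                     roi_size_mm = c(10, 10, 10)) {
  stopifnot(n_mesh >= 1L, n_fascia >= 1L)
  set.seed(seed)
  n <- n_mesh + n_fascia
  labels <- c(rep("mesh", n_mesh), rep("fascia", n_fascia))
  ext <- base_spec$shape_mm
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  depth <- stats::runif(n, 10, 30)
  # keep the ROI inside the volume along depth (0.8 mm centering jitter
  # plus rounding slack)
  margin <- roi_size_mm[1] / 2 + 1
  depth <- pmin(pmax(depth, margin), ext[1] - margin)
  rot <- stats::runif(n, 0, 90)
  # fascia sheets lie roughly parallel to the skin under the flat probe;
  # only the implanted mesh shows strong post-implantation spatial
  # variation (tilt, curl, shrinkage -- the in-vitro fragment gestures)
  tilt <- ifelse(labels == "mesh", stats::runif(n, 0, 25),
                 stats::runif(n, 0, 5))
  curv <- stats::runif(n, 20, 80)
  shrink <- stats::runif(n, 0.9, 1)
  # manual ROI segmentation is imperfect: the ROI center misses the sheet
  # center by up to ~1 mm in depth, so a single coronal slice may catch
  # only part of the (tilted, curved) sheet while the 3D ROI keeps all
  # of it
  cz_jit <- stats::runif(n, -0.8, 0.8)
  # the confusable fascia is a thin echogenic lamella, comparable in
  # scale to the 0.5 mm mesh sheet; the host/second interface band above
  # keeps a fuller thickness
  fas_th <- stats::runif(n, 0.6, 1.0)
  band_th <- stats::runif(n, 0.9, 1.4)
  # per-sample echogenicity: patients and gain settings differ, which
  # destabilizes amplitude-sensitive co-occurrence features
  echo <- stats::runif(n, 0.7, 1.3) * base_spec$echogenicity
  host_off <- stats::runif(n, 1.2, 2.2)
  cx <- ext[2] / 2
  cy <- ext[3] / 2
  sac_x <- ifelse(labels == "mesh",
                  pmin(pmax(cx + stats::rnorm(n, 0, 3), 0), ext[2]),
                  stats::runif(n, 0, ext[2]))
  sac_y <- ifelse(labels == "mesh",
                  pmin(pmax(cy + stats::rnorm(n, 0, 3), 0), ext[3]),
                  stats::runif(n, 0, ext[3]))
  ids <- sprintf("%s_%03d", labels, stats::ave(seq_len(n), labels,
                                               FUN = seq_along))
  paths <- if (!is.null(out_dir))
    file.path(out_dir, paste0(ids, ".nii.gz")) else rep(NA_character_, n)
  samples <- data.frame(
    sample_id = ids, volume_path = paths,
    cz_mm = depth + cz_jit, cx_mm = cx, cy_mm = cy,
    label = labels, sac_cx_mm = sac_x, sac_cy_mm = sac_y,
    stringsAsFactors = FALSE)
  volumes <- NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (render) {
    volumes <- vector("list", n)
    names(volumes) <- ids
    for (i in seq_len(n)) {
      spec_i <- base_spec
      spec_i$seed <- sub_seeds[i]
      spec_i$depth_mm <- depth[i]
      bg <- make_speckle_volume(spec_i)
      spec_i$echogenicity <- max(1.2, echo[i])
      spec_i$fascia_thickness_mm <- fas_th[i]
      spec_i$tilt_deg <- tilt[i]
      if (labels[i] == "mesh") {
        # implanted mesh lies against the abdominal-wall fascia (onlay /
        # preperitoneal placement): compose a fascia band 1-2 mm above the
        # pore lattice, parallel to it, with the same echogenicity. In
        # sectional (axial/sagittal) views both classes then render as a
        # linear hyperechoic area; only the coronal plane at mesh depth
        # shows the pore texture
        spec_i$scene <- "mesh"
        spec_i$rotation_deg <- rot[i]
        spec_i$curvature_radius_mm <- curv[i]
        spec_i$shrink_factor <- shrink[i]
        spec_host <- spec_i
        spec_host$depth_mm <- depth[i] - host_off[i]
        spec_host$fascia_thickness_mm <- band_th[i]
        bg2 <- add_fascia_sheet(bg, spec_host)$volume
        # the implanted mesh overlaps the fascia lamella: sectional views
        # mix both. Filaments are composed into the patchy lamella by
        # amplitude saturation (voxelwise max of the two echoes, filament
        # matched to the lamella's peak gain), so amplitude alone cannot
        # separate the classes -- only the periodic arrangement can
        lam <- add_fascia_sheet(bg2, spec_i)
        # filaments protrude slightly above the lamella's brightest patches
        spec_m <- spec_i
        spec_m$echogenicity <- 1.3 * spec_i$echogenicity
        mesh <- add_mesh_sheet(bg2, spec_m)
        res <- lam
        res$volume <- ultrasound_volume(
          pmax(lam$volume$data, mesh$volume$data), lam$volume$spacing)
        res$mesh_mask <- mesh$mesh_mask
        res$fascia_mask <- lam$fascia_mask & !mesh$mesh_mask
      } else {
        # the abdominal wall is layered in every patient: fascia samples
        # also carry a second interface band at the same offset the mesh
        # host band uses, so both classes show the same layered sectional
        # appearance
        spec_i$scene <- "fascia"
        spec_2 <- spec_i
        spec_2$depth_mm <- depth[i] - host_off[i]
        spec_2$fascia_thickness_mm <- band_th[i]
        bg2 <- add_fascia_sheet(bg, spec_2)$volume
        res <- add_fascia_sheet(bg2, spec_i)
      }
      # B-mode display log-compression: the analyzed images are the
      # scanner's compressed display, not the raw envelope; compression
      # removes most of the amplitude-range cue between classes
      res$volume <- ultrasound_volume(
        log10(1 + 10 * res$volume$data / spec_i$speckle_scale),
        res$volume$spacing)
      res$sac_center_mm <- c(sac_x[i], sac_y[i])
      volumes[[i]] <- res
      if (!is.null(out_dir)) write_nifti(res$volume, paths[i])
    }
  }
  if (!is.null(out_dir)) {
    utils::write.csv(samples, file.path(out_dir, "rois.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_mesh = n_mesh, n_fascia = n_fascia,
           base_spec = unclass(base_spec)),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(samples = samples, volumes = volumes, seed = seed)
}
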