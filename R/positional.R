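# Non-texture features: scan depth (f39) and hernia-sac proximity (f40).
#
# Neither feature is defined by a formula in the source literature; these
# are the simplest reconstructions of "scanning depth of the ROI" and
# "coronal plane position relative to the hernia sac" (see the methods
# vignette).

#' Scan-depth feature (f39)
#'
#' Depth of the ROI centroid below the probe face, in mm: the depth of a
#' voxel with 0-based index i is (i + 0.5) * spacing.
#'
#' @param roi a `roi3d`.
#' @param volume the parent `us_volume` (spacing source; the ROI must come
#'   from it).
#' @return depth in mm (nonnegative scalar).
#' @export
depth_feature <- function(roi, volume) {
  stopifnot(inherits(roi, "roi3d"), inherits(volume, "us_volume"))
  center_idx <- roi$origin[1] + (roi$size[1] - 1) / 2
  unname((center_idx + 0.5) * volume$spacing["z"])
}

#' Hernia-sac proximity feature (f40)
#'
#' Euclidean distance in the coronal plane between the ROI centroid and
#' the hernia-sac centroid, normalized by the coronal field-of-view
#' diagonal so the value lies in [0, 1]. A missing annotation yields `NA`
#' (the sample is then excluded from that feature's selection input).
#'
#' @param roi a `roi3d`.
#' @param sac_center_mm coronal sac centroid `c(width_mm, sweep_mm)`, or
#'   `NULL`/`NA` if not annotated.
#' @param volume the parent `us_volume`.
#' @return normalized distance in [0, 1], or `NA_real_`.
#' @export
sac_distance_feature <- function(roi, sac_center_mm, volume) {
  stopifnot(inherits(roi, "roi3d"), inherits(volume, "us_volume"))
  if (is.null(sac_center_mm) || any(is.na(sac_center_mm)))
    return(NA_real_)
  sac_center_mm <- as.numeric(sac_center_mm)
  stopifnot(length(sac_center_mm) == 2L)
  sp <- volume$spacing
  cx <- (roi$origin[2] + (roi$size[2] - 1) / 2 + 0.5) * sp["x"]
  cy <- (roi$origin[3] + (roi$size[3] - 1) / 2 + 0.5) * sp["y"]
  ext <- volume_extent_mm(volume)
  diag_mm <- sqrt(ext[2]^2 + ext[3]^2)
  unname(sqrt((cx - sac_center_mm[1])^2 + (cy - sac_center_mm[2])^2) /
           diag_mm)
}
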