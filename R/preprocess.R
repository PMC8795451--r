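#' Clip Hounsfield units and rescale to 0-255
#'
#' CT attenuation is clipped to the lung window `[-1200, 600]` HU and mapped
#' linearly onto `[0, 255]`: `v -> (clip(v, -1200, 600) + 1200) / 1800 * 255`.
#' The operation is monotone non-decreasing and idempotent on already-clipped
#' data (up to the unit tag).
#'
#' @param vol a [volume()] in HU.
#' @return A [volume()] with `unit = "normalized_0_255"`.
#' @examples
#' v <- volume(array(c(-1200, -300, 600, -2000), c(4, 1, 1)))
#' clip_and_scale(v)$voxels[, 1, 1]  # 0, 127.5, 255, 0
#' @export
clip_and_scale <- function(vol) {
  stopifnot(inherits(vol, "volume"))
  if (vol$unit != "HU")
    stop("clip_and_scale expects a HU volume, got unit ", vol$unit)
  v <- (pmin(pmax(vol$voxels, -1200), 600) + 1200) / 1800 * 255
  dim(v) <- dim(vol$voxels)
  volume(v, vol$spacing, vol$origin, unit = "normalized_0_255")
}

# Offsets of a discrete ball of given voxel radius, as an n x 3 integer matrix.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(d1 = -r:r, d2 = -r:r, d3 = -r:r)
  keep <- g$d1^2 + g$d2^2 + g$d3^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

dilate3 <- function(mask, radius) {
  d <- dim(mask)
  out <- cpp_dilate(as.integer(mask), d[1], d[2], d[3], ball_offsets(radius))
  array(out != 0, d)
}

erode3 <- function(mask, radius) {
  d <- dim(mask)
  out <- cpp_erode(as.integer(mask), d[1], d[2], d[3], ball_offsets(radius))
  array(out != 0, d)
}

# Morphological closing with a ball structuring element.
close3 <- function(mask, radius) erode3(dilate3(mask, radius), radius)

# Replace every 2D-connected component of each axial slice by its filled
# convex hull. Thresholding carves soft-tissue-density structures (vessels,
# juxtapleural nodules) out of the air-based lung mask; bites that touch the
# pleural boundary are not holes and survive hole filling, but the per-slice
# lung cross-section is near-convex, so the slice-wise convex closure
# recovers them. Left and right lungs are closed separately (2D components).
convex_close_slices <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (iz in seq_len(d[1])) {
    sl <- mask[iz, , ]
    if (!any(sl)) next
    lab <- array(cpp_label6(as.integer(sl), d[2], d[3], 1L), c(d[2], d[3]))
    filled <- sl
    for (cc in seq_len(max(lab))) {
      pts <- which(lab == cc, arr.ind = TRUE)
      if (nrow(pts) < 3) next
      h <- grDevices::chull(pts[, 1], pts[, 2])
      vy <- pts[h, 1]; vx <- pts[h, 2]
      lo <- pmax(c(min(vy), min(vx)), 1)
      hi <- pmin(c(max(vy), max(vx)), c(d[2], d[3]))
      grid <- expand.grid(y = lo[1]:hi[1], x = lo[2]:hi[2])
      inside <- point_in_polygon(grid$y, grid$x, vy, vx)
      filled[cbind(grid$y[inside], grid$x[inside])] <- TRUE
    }
    out[iz, , ] <- filled
  }
  out
}

# crossing-number point-in-polygon test, vectorized over points
point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    dy <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses) && dy != 0) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / dy + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Fill 2D holes in every axial (z = const) slice: any background region of a
# slice not connected to the slice border becomes foreground.
fill_holes_axial <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (iz in seq_len(d[1])) {
    sl <- mask[iz, , ]
    bg <- !sl
    lab <- array(cpp_label6(as.integer(bg), d[2], d[3], 1L), c(d[2], d[3]))
    border <- unique(c(lab[1, ], lab[d[2], ], lab[, 1], lab[, d[3]]))
    border <- border[border != 0]
    holes <- bg & !(lab %in% border)
    dim(holes) <- c(d[2], d[3])
    out[iz, , ] <- sl | holes
  }
  out
}

#' Segment the lung parenchyma of a HU volume
#'
#' Thresholding plus morphology: binarize air-like voxels at `threshold_hu`
#' (default -320 HU), discard connected components that touch the axial
#' (x/y) volume border (body-exterior air), keep the largest one or two
#' remaining components (the lungs), close with a ball of radius
#' `closing_radius` voxels, fill axial-slice holes, and dilate by
#' `dilation_radius` voxels so juxtapleural nodules stay inside the mask.
#' Deterministic for fixed input. A volume with no lung-like region yields an
#' empty mask carrying a warning, not an error.
#'
#' @param vol a [volume()] in HU.
#' @param threshold_hu binarization threshold (HU), default -320.
#' @param closing_radius ball radius (voxels) of the morphological closing.
#' @param dilation_radius final dilation radius (voxels).
#' @param keep_components number of interior low-attenuation components kept
#'   (1-2; both lungs may form a single component).
#' @param convex_slices close each axial slice component to its convex hull
#'   before the final dilation. Thresholding carves juxtapleural nodules out
#'   of the air mask and their pleural bites are not holes; the slice-wise
#'   convex closure recovers them. Disable for strongly non-convex real
#'   anatomy if overfilling near the mediastinum is a concern.
#' @return A [lung_mask()].
#' @export
segment_lung <- function(vol, threshold_hu = -320, closing_radius = 3,
                         dilation_radius = 2, keep_components = 2,
                         convex_slices = TRUE) {
  stopifnot(inherits(vol, "volume"))
  if (vol$unit != "HU")
    stop("segment_lung expects a HU volume, got unit ", vol$unit)
  d <- dim(vol$voxels)
  air <- vol$voxels < threshold_hu
  lab <- array(cpp_label6(as.integer(air), d[1], d[2], d[3]), d)

  # components touching the axial border are exterior air, not lung
  border <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border <- border[border != 0]
  interior <- lab
  interior[interior %in% border] <- 0L

  sizes <- tabulate(interior)
  if (!length(sizes) || !any(sizes > 0)) {
    return(lung_mask(array(FALSE, d),
                     warning = "no lung-like low-attenuation region found"))
  }
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(keep_components, sum(sizes > 0)))]
  # drop trailing kept components that are tiny relative to the largest
  keep <- keep[sizes[keep] >= 0.05 * sizes[keep[1]]]
  m <- array(interior %in% keep, d)
  m <- close3(m, closing_radius)
  m <- fill_holes_axial(m)
  if (convex_slices) m <- convex_close_slices(m)
  m <- dilate3(m, dilation_radius)
  lung_mask(m)
}

#' Mask out non-lung tissue and crop to the lung bounding box
#'
#' Voxels outside the mask are set to `pad_value` (170 on the 0-255 scale,
#' about soft tissue, so crop borders do not create artificial air-tissue
#' edges); the volume is cropped to the mask bounding box plus `margin`
#' voxels, and the origin is updated so world coordinates of retained voxels
#' are unchanged.
#'
#' @param vol a [volume()] (typically already [clip_and_scale()]d).
#' @param mask a [lung_mask()] congruent with `vol`.
#' @param pad_value fill value for masked-out voxels.
#' @param margin bounding-box margin in voxels.
#' @return A [volume()] covering the masked, cropped region.
#' @export
apply_mask_and_crop <- function(vol, mask, pad_value = 170, margin = 8) {
  stopifnot(inherits(vol, "volume"), inherits(mask, "lung_mask"))
  d <- dim(vol$voxels)
  if (!identical(d, dim(mask$voxels)))
    stop("volume and mask shapes differ: ", paste(d, collapse = "x"), " vs ",
         paste(dim(mask$voxels), collapse = "x"))
  v <- vol$voxels
  v[!mask$voxels] <- pad_value
  if (!any(mask$voxels)) {
    out <- volume(v, vol$spacing, vol$origin, unit = vol$unit)
    out$mask <- mask$voxels
    return(out)
  }
  idx <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  cropped <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # origin is (x,y,z); lo is (z,y,x) 1-based
  shift_xyz <- (rev(lo) - 1) * rev(vol$spacing)
  out <- volume(cropped, vol$spacing, vol$origin + shift_xyz, unit = vol$unit)
  # carry the cropped parenchyma mask: detection restricts candidates to it
  out$mask <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto a grid of `target_spacing` mm (default 1 mm,
#' so the mm-denominated anchor cubes coincide with voxels). The world
#' position of voxel `(0,0,0)` (the origin) is unchanged and feature world
#' positions are preserved to within one voxel.
#'
#' @param vol a [volume()].
#' @param target_spacing target spacing in mm (scalar, isotropic).
#' @return A resampled [volume()].
#' @export
resample_isotropic <- function(vol, target_spacing = 1) {
  stopifnot(inherits(vol, "volume"), target_spacing > 0)
  d <- dim(vol$voxels)
  if (all(abs(vol$spacing - target_spacing) < 1e-9)) return(vol)
  newd <- pmax(as.integer(round(d * vol$spacing / target_spacing)), 1L)
  scale <- target_spacing / vol$spacing   # input voxels per output voxel, (z,y,x)
  out <- cpp_trilinear(as.numeric(vol$voxels), d[1], d[2], d[3],
                       newd[1], newd[2], newd[3],
                       scale, c(0, 0, 0))
  volume(array(out, newd), rep(target_spacing, 3), vol$origin, unit = vol$unit)
}

#' Crop a cubic patch with pad fill and patch-local annotations
#'
#' Out-of-bounds regions are filled with `pad_value`. Annotations are
#' re-expressed in patch voxel coordinates; an annotation belongs to the
#' patch iff its center lies inside (its diameter may overhang).
#'
#' @param vol a [volume()].
#' @param center_voxel patch center, continuous `(z, y, x)` voxel indices.
#' @param size patch edge length in voxels (scalar or length 3).
#' @param annotations optional tibble in the volume voxel frame
#'   (`vz, vy, vx, diameter`, see internals of the training samplers), or
#'   NULL.
#' @param pad_value fill for out-of-bounds voxels.
#' @return list with `patch` (3D array), `annotations` (patch-frame tibble),
#'   and `offset` (voxel index, possibly negative, of patch `(0,0,0)` in the
#'   volume frame).
#' @export
crop_patch <- function(vol, center_voxel, size, annotations = NULL,
                       pad_value = 170) {
  stopifnot(inherits(vol, "volume"))
  size <- rep(as.integer(size), length.out = 3)
  d <- dim(vol$voxels)
  start <- as.integer(round(center_voxel - size / 2))   # 0-based
  patch <- array(pad_value, size)
  src_lo <- pmax(start, 0L); src_hi <- pmin(start + size, d) - 1L
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start
    patch[(dst_lo[1] + 1):(dst_lo[1] + 1 + src_hi[1] - src_lo[1]),
          (dst_lo[2] + 1):(dst_lo[2] + 1 + src_hi[2] - src_lo[2]),
          (dst_lo[3] + 1):(dst_lo[3] + 1 + src_hi[3] - src_lo[3])] <-
      vol$voxels[(src_lo[1] + 1):(src_hi[1] + 1),
                 (src_lo[2] + 1):(src_hi[2] + 1),
                 (src_lo[3] + 1):(src_hi[3] + 1)]
  }
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- annotations
    if (nrow(ann)) {
      ann$vz <- ann$vz - start[1]
      ann$vy <- ann$vy - start[2]
      ann$vx <- ann$vx - start[3]
      inside <- ann$vz >= 0 & ann$vz < size[1] &
        ann$vy >= 0 & ann$vy < size[2] &
        ann$vx >= 0 & ann$vx < size[3]
      ann <- ann[inside, , drop = FALSE]
    }
  }
  list(patch = patch, annotations = ann, offset = start)
}
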