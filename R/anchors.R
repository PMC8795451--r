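# Anchor lattice, 3D IoU, label assignment and box encoding/decoding.
#
# Anchors are cubes of side 5, 10 and 20 mm centred on the cells of the
# detector output grid (stride 4 voxels = 4 mm at 1 mm spacing). All
# coordinates here live in the patch voxel frame: continuous 0-based voxel
# indices, which equal mm offsets at isotropic 1 mm spacing.

#' Construct the anchor lattice for an output grid
#'
#' Anchor centers sit at grid-cell centers: axis coordinate
#' `(i + 0.5) * stride - 0.5` for 0-based cell index `i`. Total anchor count
#' is `grid^3 * length(sizes)`.
#'
#' @param grid_size output grid edge (input patch edge / 4).
#' @param stride detection stride in voxels (4).
#' @param sizes anchor cube side lengths in mm.
#' @return An `anchor_grid` list with the per-axis center coordinates and
#'   sizes.
#' @export
anchor_grid <- function(grid_size, stride = 4, sizes = c(5, 10, 20)) {
  centers <- (seq_len(grid_size) - 1 + 0.5) * stride - 0.5
  structure(list(grid_size = grid_size, stride = stride, sizes = sizes,
                 centers = centers),
            class = "anchor_grid")
}

#' Intersection-over-union of axis-aligned cubes
#'
#' Boxes are cubes given by center + side length ("diameter"). Vectorized
#' over rows when centers are n x 3 matrices.
#'
#' @param center_a,center_b cube centers, length-3 vectors (any consistent
#'   axis order) or n x 3 matrices.
#' @param d_a,d_b side lengths (> 0), scalars or length-n vectors.
#' @return IoU fraction(s) in `[0, 1]`.
#' @examples
#' iou3d(c(0, 0, 0), 10, c(5, 0, 0), 10)  # 1/3
#' @export
iou3d <- function(center_a, d_a, center_b, d_b) {
  a <- to_mat3(center_a); b <- to_mat3(center_b)
  stopifnot(all(d_a > 0), all(d_b > 0))
  ha <- d_a / 2; hb <- d_b / 2
  ov <- function(j) pmax(0, pmin(a[, j] + ha, b[, j] + hb) -
                              pmax(a[, j] - ha, b[, j] - hb))
  inter <- ov(1) * ov(2) * ov(3)
  inter / (d_a^3 + d_b^3 - inter)
}

#' Assign classification labels to every anchor of a patch
#'
#' An anchor is positive (`p* = 1`) when its best IoU with any annotation
#' exceeds `pos_iou` (0.5), negative (`p* = 0`) when its IoU with all
#' annotations is below `neg_iou` (0.02), and ignored otherwise (ignored
#' anchors contribute nothing to the loss). With `force_match = TRUE`
#' (default) every annotation additionally gets its argmax-IoU anchor forced
#' positive — without this a small nodule may generate no positive anchor at
#' all. Ties in the argmax are broken by lowest anchor index.
#'
#' @param grid an [anchor_grid()].
#' @param annotations tibble in the patch voxel frame: columns
#'   `vz, vy, vx` (continuous 0-based indices) and `diameter` (mm).
#' @param pos_iou,neg_iou the positive / negative IoU thresholds.
#' @param force_match guarantee at least one positive anchor per annotation.
#' @return list with `p_star` (array `(g, g, g, n_sizes)` of 1 / 0 / NA),
#'   `matched` (annotation row index for positives), `best_iou`.
#' @export
assign_labels <- function(grid, annotations, pos_iou = 0.5, neg_iou = 0.02,
                          force_match = TRUE) {
  g <- grid$grid_size
  na <- length(grid$sizes)
  dims <- c(g, g, g, na)
  best_iou <- array(0, dims)
  matched <- array(NA_integer_, dims)
  n_ann <- if (is.null(annotations)) 0L else nrow(annotations)
  if (n_ann > 0) {
    for (r in seq_len(n_ann)) {
      iou_r <- anchor_iou_with(grid, c(annotations$vz[r], annotations$vy[r],
                                       annotations$vx[r]),
                               annotations$diameter[r])
      better <- iou_r > best_iou
      matched[better] <- r
      best_iou[better] <- iou_r[better]
    }
  }
  p_star <- array(NA_real_, dims)
  p_star[best_iou < neg_iou] <- 0
  p_star[best_iou > pos_iou] <- 1
  if (force_match && n_ann > 0) {
    for (r in seq_len(n_ann)) {
      iou_r <- anchor_iou_with(grid, c(annotations$vz[r], annotations$vy[r],
                                       annotations$vx[r]),
                               annotations$diameter[r])
      i <- which.max(iou_r)          # ties: lowest linear index
      p_star[i] <- 1
      matched[i] <- r
      best_iou[i] <- iou_r[i]
    }
  }
  matched[is.na(p_star) | p_star == 0] <- NA_integer_
  list(p_star = p_star, matched = matched, best_iou = best_iou)
}

# IoU of every anchor with one cube (center in patch voxel frame (z,y,x),
# diameter in mm), exploiting the separable lattice: per-axis overlaps are
# combined by outer products. Returns an array (g, g, g, n_sizes).
anchor_iou_with <- function(grid, center_zyx, diameter) {
  g <- grid$grid_size
  h <- diameter / 2
  out <- array(0, c(g, g, g, length(grid$sizes)))
  for (a in seq_along(grid$sizes)) {
    s <- grid$sizes[a]
    ov_axis <- function(c0) pmax(0, pmin(grid$centers + s / 2, c0 + h) -
                                      pmax(grid$centers - s / 2, c0 - h))
    oz <- ov_axis(center_zyx[1]); oy <- ov_axis(center_zyx[2])
    ox <- ov_axis(center_zyx[3])
    inter <- outer(outer(oz, oy), ox)   # (z, y, x), z fastest
    out[, , , a] <- inter / (s^3 + diameter^3 - inter)
  }
  out
}

#' Encode / decode a box against an anchor
#'
#' The regression parameterization: per center axis `(c - c_a) / d_a`, plus
#' `log(d / d_a)` for the size, where `(c_a, d_a)` are the anchor center and
#' side. `decode_box(encode_box(c, d, ...), ...)` is exact.
#'
#' @param center box center, length-3 (any consistent axis order).
#' @param diameter box diameter (> 0).
#' @param anchor_center,anchor_d the anchor's center and side length.
#' @return `encode_box`: the 4-vector `t`; `decode_box`: list with `center`
#'   and `diameter`.
#' @examples
#' encode_box(c(5, 0, 0), 20, c(0, 0, 0), 10)  # 0.5 0 0 log(2)
#' @export
encode_box <- function(center, diameter, anchor_center, anchor_d) {
  if (diameter <= 0 || anchor_d <= 0) stop("diameters must be positive")
  c((center - anchor_center) / anchor_d, log(diameter / anchor_d))
}

#' @rdname encode_box
#' @param t regression 4-vector as returned by `encode_box`.
#' @export
decode_box <- function(t, anchor_center, anchor_d) {
  list(center = anchor_center + t[1:3] * anchor_d,
       diameter = anchor_d * exp(t[4]))
}

# Regression-target tensor aligned with the detector output packing:
# array (g, g, g, n_sizes, 4) with the last dim ordered (tz, ty, tx, tlogd).
make_regression_targets <- function(grid, labels, annotations) {
  g <- grid$grid_size
  na <- length(grid$sizes)
  targets <- array(0, c(g, g, g, na, 4))
  pos <- which(!is.na(labels$p_star) & labels$p_star == 1)
  if (!length(pos)) return(targets)
  ai <- arrayInd(pos, c(g, g, g, na))
  for (row in seq_len(nrow(ai))) {
    i <- ai[row, ]
    r <- labels$matched[pos[row]]
    anc_c <- grid$centers[i[1:3]]
    anc_d <- grid$sizes[i[4]]
    tt <- encode_box(c(annotations$vz[r], annotations$vy[r], annotations$vx[r]),
                     annotations$diameter[r], anc_c, anc_d)
    targets[i[1], i[2], i[3], i[4], ] <- tt
  }
  targets
}
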