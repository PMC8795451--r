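# Whole-scan sliding-window inference, probability filtering, 3D NMS and
# FPR rescoring.

#' Detect candidates in a whole preprocessed scan
#'
#' Tiles the volume with overlapping cubic patches (stride `patch - 2 *
#' margin`, i.e. 64 for 96^3 patches), runs the detector on each tile, and
#' decodes per-anchor predictions above `prob_threshold` to world-mm
#' candidates. Detections whose centers fall in the outer `margin` voxels of
#' a tile are discarded unless that tile face lies on the volume boundary,
#' which de-duplicates tile seams while keeping full coverage. Volumes
#' smaller than one patch are pad-extended.
#'
#' @param net a trained [build_detector()] network.
#' @param vol a preprocessed [volume()] (masked, cropped, 0-255 scale,
#'   isotropic 1 mm spacing).
#' @param series_id series identifier for the output rows.
#' @param prob_threshold keep detections with probability strictly greater
#'   than this (default 0.12).
#' @param margin seam margin in voxels; default `(patch - stride) / 2` with
#'   stride `patch - patch/3` (96 -> 64).
#' @param pad_value fill for out-of-bounds patch voxels.
#' @return A candidate tibble: `series_id, x, y, z, diameter, probability`
#'   (world mm).
#' @export
sliding_window_detect <- function(net, vol, series_id = "scan",
                                  prob_threshold = 0.12, margin = NULL,
                                  pad_value = 170) {
  stopifnot(inherits(vol, "volume"))
  cfg <- net$config
  patch <- cfg$input_size
  if (is.null(margin)) margin <- patch / 6       # 96 -> 16, 32 -> ~5
  margin <- floor(margin)
  stride <- patch - 2 * margin
  d <- dim(vol$voxels)
  sz <- tile_starts(d[1], patch, stride)
  sy <- tile_starts(d[2], patch, stride)
  sx <- tile_starts(d[3], patch, stride)
  grid <- anchor_grid(patch / cfg$stride, cfg$stride, cfg$anchors)
  out <- list()
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    cp <- crop_patch(vol, c(z0, y0, x0) + patch / 2, patch,
                     pad_value = pad_value)
    pred <- detector_forward(net, normalize_patch(cp$patch), training = FALSE)
    rec <- detector_output_to_grid_predictions(pred, cfg$anchors)
    rec <- rec[rec$p > prob_threshold, , drop = FALSE]
    if (!nrow(rec)) next
    # decode to patch voxel coords
    cz <- grid$centers[rec$gz + 1] + rec$tz * rec$anchor_mm
    cy <- grid$centers[rec$gy + 1] + rec$ty * rec$anchor_mm
    cx <- grid$centers[rec$gx + 1] + rec$tx * rec$anchor_mm
    dd <- rec$anchor_mm * exp(rec$tlogd)
    # seam margin: drop centers in the outer margin of interior faces
    keep <- rep(TRUE, length(cz))
    lo_ok <- function(c0, s0) c0 >= margin | s0 == 0
    hi_ok <- function(c0, s0, n) c0 < patch - margin | s0 + patch >= n
    keep <- keep & lo_ok(cz, z0) & hi_ok(cz, z0, d[1]) &
      lo_ok(cy, y0) & hi_ok(cy, y0, d[2]) &
      lo_ok(cx, x0) & hi_ok(cx, x0, d[3])
    if (!any(keep)) next
    vzyx <- cbind(cz + z0, cy + y0, cx + x0)[keep, , drop = FALSE]
    # restrict candidates to the lung parenchyma when the volume carries
    # its mask (centers in the padded exterior are not lung findings)
    if (!is.null(vol$mask)) {
      dm <- dim(vol$mask)
      ri <- pmin(pmax(round(vzyx), 0), matrix(dm - 1, nrow(vzyx), 3,
                                              byrow = TRUE))
      inmask <- vol$mask[ri + 1]
      dim(inmask) <- NULL
      vzyx <- vzyx[inmask, , drop = FALSE]
      keep[keep] <- inmask
      if (!nrow(vzyx)) next
    }
    w <- voxel_to_world(vol, vzyx)
    out[[length(out) + 1]] <- tibble::tibble(
      series_id = series_id, x = w[, 1], y = w[, 2], z = w[, 3],
      diameter = dd[keep], probability = rec$p[keep])
  }
  if (!length(out)) {
    return(tibble::tibble(series_id = character(), x = numeric(),
                          y = numeric(), z = numeric(), diameter = numeric(),
                          probability = numeric()))
  }
  dplyr::bind_rows(out)
}

# Network input scaling: 0-255 patch -> [-1, 1].
normalize_patch <- function(patch) (patch - 128) / 128

# 0-based tile start offsets covering [0, n): stride-spaced, with a final
# tile flushed to the end so every voxel is inside at least one tile.
tile_starts <- function(n, patch, stride) {
  if (n <= patch) return(0L)
  s <- seq(0L, n - patch, by = stride)
  if (tail(s, 1) < n - patch) s <- c(s, n - patch)
  as.integer(s)
}

#' Probability filtering and greedy 3D non-maximum suppression
#'
#' Drops candidates with probability `<= prob_threshold` (strictly "larger
#' than 0.12" survives), sorts by descending probability (ties broken by
#' coordinates, so the result is deterministic), and greedily keeps a
#' candidate iff its cube IoU with every already-kept candidate of the same
#' series is `<= iou_threshold`. Idempotent.
#'
#' @param candidates candidate tibble (world mm).
#' @param prob_threshold probability cut (0.12).
#' @param iou_threshold NMS IoU cut (0.1).
#' @return The filtered candidate tibble.
#' @export
filter_and_nms <- function(candidates, prob_threshold = 0.12,
                           iou_threshold = 0.1) {
  cand <- candidates[candidates$probability > prob_threshold, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  cand <- dplyr::arrange(cand, .data$series_id, dplyr::desc(.data$probability),
                         .data$x, .data$y, .data$z)
  kept <- lapply(split(cand, cand$series_id), function(cs) {
    n <- nrow(cs)
    keep <- logical(n)
    ctr <- cbind(cs$x, cs$y, cs$z)
    for (i in seq_len(n)) {
      ki <- which(keep)
      if (!length(ki)) { keep[i] <- TRUE; next }
      ious <- iou3d(matrix(ctr[i, ], length(ki), 3, byrow = TRUE),
                    cs$diameter[i], ctr[ki, , drop = FALSE], cs$diameter[ki])
      keep[i] <- all(ious <= iou_threshold)
    }
    cs[keep, , drop = FALSE]
  })
  out <- dplyr::bind_rows(kept)
  dplyr::arrange(out, .data$series_id, dplyr::desc(.data$probability),
                 .data$x, .data$y, .data$z)
}

#' Rescore candidates with the false-positive-reduction network
#'
#' Crops a cube (48^3 for the full profile) at each candidate's center from
#' the preprocessed volume, pads when the cube exceeds the volume, and
#' replaces the candidate's probability with the classifier's sigmoid
#' output. Never drops a candidate; the result is re-sorted by probability.
#'
#' @param candidates candidate tibble for one series (world mm).
#' @param vol the series' preprocessed [volume()].
#' @param net a trained [build_fpr()] network.
#' @param fov_mm physical edge length of the cropped cube (mm); when it
#'   exceeds the network input size the crop is resampled down, trading
#'   resolution for context. Defaults to the network input size (48 mm at
#'   48^3 for the full profile).
#' @param pad_value fill for out-of-bounds cube voxels.
#' @param sort re-sort by the new probability (default); FALSE preserves
#'   the input row order.
#' @return The rescored candidate tibble.
#' @export
rescore_with_fpr <- function(candidates, vol, net, fov_mm = NULL,
                             pad_value = 170, sort = TRUE) {
  if (!nrow(candidates)) return(candidates)
  vox <- world_to_voxel(vol, cbind(candidates$x, candidates$y, candidates$z))
  vox <- matrix(vox, ncol = 3)
  p <- vapply(seq_len(nrow(candidates)), function(i) {
    cube <- fpr_cube(vol, vox[i, ], net$config$input_size, fov_mm, pad_value)
    fpr_probability(net, cube)
  }, numeric(1))
  out <- candidates
  out$probability <- p
  if (!sort) return(out)
  dplyr::arrange(out, dplyr::desc(.data$probability))
}

#' Merge same-object candidates by center distance
#'
#' Cube-IoU suppression cannot merge detections of one object proposed at
#' very different scales (a 3 mm and a 12 mm box on the same nodule overlap
#' almost nothing), so detectors emit cross-scale duplicates. This pass
#' keeps candidates in descending probability order and drops any candidate
#' whose center lies within the radius of an already-kept candidate of the
#' same series — the same center-within-radius geometry as the hit
#' criterion.
#'
#' @param candidates candidate tibble (world mm).
#' @return The de-duplicated tibble, sorted by series and probability.
#' @export
merge_duplicates <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  cand <- dplyr::arrange(candidates, .data$series_id,
                         dplyr::desc(.data$probability), .data$x, .data$y,
                         .data$z)
  kept <- lapply(split(cand, cand$series_id), function(cs) {
    n <- nrow(cs)
    keep <- logical(n)
    for (i in seq_len(n)) {
      ki <- which(keep)
      if (length(ki)) {
        dist <- sqrt((cs$x[ki] - cs$x[i])^2 + (cs$y[ki] - cs$y[i])^2 +
                       (cs$z[ki] - cs$z[i])^2)
        if (any(dist <= pmax(cs$diameter[ki], cs$diameter[i]) / 2)) next
      }
      keep[i] <- TRUE
    }
    cs[keep, , drop = FALSE]
  })
  dplyr::bind_rows(kept)
}

#' Keep the top candidates of each scan
#'
#' Bounds the average candidates per scan handed to the second stage by
#' keeping the `n_per_scan` highest-probability candidates of every series.
#'
#' @param candidates candidate tibble.
#' @param n_per_scan cap per series.
#' @return The capped tibble.
#' @export
top_candidates <- function(candidates, n_per_scan = 250) {
  dplyr::bind_rows(lapply(split(candidates, candidates$series_id), function(cs) {
    cs[order(-cs$probability), , drop = FALSE][seq_len(min(nrow(cs), n_per_scan)), ]
  }))
}

# Normalized FPR input cube at a voxel center: crop fov_mm (defaults to the
# input size) and resample to the network grid when they differ.
fpr_cube <- function(vol, center_voxel, input_size, fov_mm = NULL,
                     pad_value = 170) {
  if (is.null(fov_mm)) fov_mm <- input_size
  cp <- crop_patch(vol, center_voxel, fov_mm, pad_value = pad_value)$patch
  if (fov_mm != input_size) {
    sc <- rep(fov_mm / input_size, 3)
    cp <- array(cpp_trilinear(cp, fov_mm, fov_mm, fov_mm,
                              input_size, input_size, input_size,
                              sc, (sc - 1) / 2),
                c(input_size, input_size, input_size))
  }
  normalize_patch(cp)
}
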