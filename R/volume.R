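#' 3D CT volume with world-coordinate metadata
#'
#' A `volume` couples a 3D voxel grid with the world-coordinate metadata
#' needed to map between voxel indices and scanner (patient) millimetre
#' coordinates. Voxels are indexed `(z, y, x)` with `z` the fastest-varying
#' array dimension; `spacing` is in mm per voxel along `(z, y, x)`; `origin`
#' is the world position, in `(x, y, z)` mm, of voxel `(0, 0, 0)` — the same
#' conventions as the LUNA16 annotation files.
#'
#' @param voxels 3D numeric array indexed `(z, y, x)`.
#' @param spacing numeric length 3, mm per voxel along `(z, y, x)`; all
#'   strictly positive.
#' @param origin numeric length 3, world `(x, y, z)` mm of voxel `(0,0,0)`.
#' @param unit intensity unit, `"HU"` (Hounsfield) or `"normalized_0_255"`.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1), origin = c(0, 0, 0))
#' dim(v$voxels)
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   unit = c("HU", "normalized_0_255")) {
  unit <- match.arg(unit)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("spacing components must be strictly positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), unit = unit),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %d x %d x %d voxels (z,y,x), spacing %s mm, origin (%s) mm, unit %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", "), x$unit))
  invisible(x)
}

#' Convert between world (mm) and voxel coordinates
#'
#' World coordinates are `(x, y, z)` mm; voxel coordinates are continuous
#' 0-based `(z, y, x)` indices. `voxel = (world - origin) / spacing` per axis
#' with the `(x,y,z) -> (z,y,x)` axis reorder; `voxel_to_world` is the exact
#' inverse.
#'
#' @param vol a [volume()].
#' @param world numeric length 3 `(x, y, z)` mm, or an n x 3 matrix.
#' @return `world_to_voxel`: continuous `(z, y, x)` voxel indices (vector or
#'   n x 3 matrix); `voxel_to_world`: `(x, y, z)` mm.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), origin = c(-100, -100, -200))
#' world_to_voxel(v, c(-90, -100, -200))  # (0, 0, 10)
#' @export
world_to_voxel <- function(vol, world) {
  w <- to_mat3(world)
  sp_xyz <- rev(vol$spacing)                # spacing reordered to (x,y,z)
  v_xyz <- sweep(sweep(w, 2, vol$origin, "-"), 2, sp_xyz, "/")
  out <- v_xyz[, c(3, 2, 1), drop = FALSE]  # -> (z,y,x)
  if (is.null(dim(world))) drop(out) else out
}

#' @rdname world_to_voxel
#' @param voxel numeric length 3 `(z, y, x)` continuous index, or n x 3 matrix.
#' @export
voxel_to_world <- function(vol, voxel) {
  v <- to_mat3(voxel)[, c(3, 2, 1), drop = FALSE]  # -> (x,y,z)
  sp_xyz <- rev(vol$spacing)
  out <- sweep(sweep(v, 2, sp_xyz, "*"), 2, vol$origin, "+")
  if (is.null(dim(voxel))) drop(out) else out
}

to_mat3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else {
    stopifnot(ncol(x) == 3L)
    unname(as.matrix(x))
  }
}

#' Binary lung mask congruent with a volume
#'
#' @param voxels logical/integer 3D array, same shape as the parent volume.
#' @param warning optional character carried when segmentation found nothing.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, warning = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  structure(list(voxels = voxels != 0, warning = warning), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels in mask (%.1f%%)%s\n",
              format(sum(x$voxels), big.mark = ","),
              100 * mean(x$voxels),
              if (!is.null(x$warning)) paste0(" [warning: ", x$warning, "]") else ""))
  invisible(x)
}
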