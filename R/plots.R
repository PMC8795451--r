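# Simple overlay rendering of an axial slice with annotation / candidate
# rings.

#' Plot an axial slice with nodule overlays
#'
#' Renders the axial slice nearest `z_mm` (or the slice through the first
#' annotation when NULL) as a grayscale raster with circles at annotation
#' (solid) and candidate (dashed) positions whose in-plane radius follows
#' from the sphere-plane intersection.
#'
#' @param vol a [volume()].
#' @param annotations optional annotation tibble (world mm).
#' @param candidates optional candidate tibble (world mm).
#' @param z_mm world z of the slice to show, or NULL.
#' @return A ggplot object.
#' @export
plot_slice_overlay <- function(vol, annotations = NULL, candidates = NULL,
                               z_mm = NULL) {
  stopifnot(inherits(vol, "volume"))
  if (is.null(z_mm)) {
    z_mm <- if (!is.null(annotations) && nrow(annotations)) annotations$z[1] else
      voxel_to_world(vol, (dim(vol$voxels) - 1) / 2)[3]
  }
  iz <- round(world_to_voxel(vol, c(vol$origin[1], vol$origin[2], z_mm))[1])
  iz <- min(max(iz, 0), dim(vol$voxels)[1] - 1)
  sl <- vol$voxels[iz + 1, , ]
  d <- dim(sl)
  df <- tidyr::expand_grid(vy = seq_len(d[1]) - 1, vx = seq_len(d[2]) - 1)
  df$value <- as.vector(t(sl))   # vx fastest in expand_grid order
  xw <- vol$origin[1] + (seq_len(d[2]) - 1) * rev(vol$spacing)[1]
  yw <- vol$origin[2] + (seq_len(d[1]) - 1) * vol$spacing[2]
  df$x <- xw[df$vx + 1]; df$y <- yw[df$vy + 1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice z = %.1f mm", z_mm)) +
    ggplot2::theme_minimal()
  ring <- function(tb, linetype) {
    tb <- tb[abs(tb$z - z_mm) <= tb$diameter / 2, , drop = FALSE]
    if (!nrow(tb)) return(NULL)
    r <- sqrt(pmax((tb$diameter / 2)^2 - (tb$z - z_mm)^2, 0.25))
    circ <- dplyr::bind_rows(lapply(seq_len(nrow(tb)), function(i) {
      th <- seq(0, 2 * pi, length.out = 60)
      tibble::tibble(id = i, x = tb$x[i] + r[i] * cos(th),
                     y = tb$y[i] + r[i] * sin(th))
    }))
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$id),
                       inherit.aes = FALSE, colour = "red",
                       linetype = linetype)
  }
  if (!is.null(annotations)) p <- p + ring(annotations, "solid")
  if (!is.null(candidates)) p <- p + ring(candidates, "dashed")
  p
}
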