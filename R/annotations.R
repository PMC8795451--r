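#' Read and write LUNA16-dialect annotation and candidate CSVs
#'
#' Annotation files carry one nodule per row with header
#' `seriesuid,coordX,coordY,coordZ,diameter_mm`; candidate files append a
#' `probability` column. In memory both are tibbles with tidy column names
#' `series_id, x, y, z, diameter` (+ `probability`), coordinates in world mm.
#'
#' @param path CSV file path.
#' @return A tibble with one row per nodule / candidate.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation CSV missing column(s): ", paste(missing, collapse = ", "))
  tibble::tibble(series_id = as.character(df$seriesuid),
                 x = df$coordX, y = df$coordY, z = df$coordZ,
                 diameter = df$diameter_mm)
}

#' @rdname read_annotations
#' @param annotations tibble with columns `series_id, x, y, z, diameter`.
#' @export
write_annotations <- function(annotations, path) {
  out <- tibble::tibble(seriesuid = annotations$series_id,
                        coordX = annotations$x, coordY = annotations$y,
                        coordZ = annotations$z,
                        diameter_mm = annotations$diameter)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_candidates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm", "probability")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("candidate CSV missing column(s): ", paste(missing, collapse = ", "))
  tibble::tibble(series_id = as.character(df$seriesuid),
                 x = df$coordX, y = df$coordY, z = df$coordZ,
                 diameter = df$diameter_mm, probability = df$probability)
}

#' @rdname read_annotations
#' @param candidates tibble with columns `series_id, x, y, z, diameter,
#'   probability`.
#' @export
write_candidates <- function(candidates, path) {
  out <- tibble::tibble(seriesuid = candidates$series_id,
                        coordX = candidates$x, coordY = candidates$y,
                        coordZ = candidates$z, diameter_mm = candidates$diameter,
                        probability = candidates$probability)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Annotations of one series expressed in a volume's continuous voxel frame:
# columns vz, vy, vx (0-based voxel indices) + diameter (mm).
annotations_to_voxel <- function(vol, annotations) {
  if (nrow(annotations) == 0) {
    return(tibble::tibble(vz = numeric(), vy = numeric(), vx = numeric(),
                          diameter = numeric()))
  }
  v <- world_to_voxel(vol, cbind(annotations$x, annotations$y, annotations$z))
  tibble::tibble(vz = v[, 1], vy = v[, 2], vx = v[, 3],
                 diameter = annotations$diameter)
}
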