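#' Read and write MetaImage (.mhd/.raw) volumes
#'
#' MetaImage is the volume format LUNA16 ships: a plain-text `.mhd` header of
#' `Key = value` lines plus a raw little-endian binary file. In the header and
#' raw file the axis order is `(x, y, z)` with x fastest; on read the grid is
#' reordered to this package's `(z, y, x)` array convention.
#'
#' `write_metaimage` defaults to `MET_DOUBLE` storage so a write/read round
#' trip reproduces voxels, spacing and origin exactly.
#'
#' @param path path to the `.mhd` header file.
#' @param unit intensity unit to tag the volume with (the format itself does
#'   not carry one); defaults to `"HU"`.
#' @return `read_metaimage`: a [volume()]. `write_metaimage`: `path`,
#'   invisibly.
#' @export
read_metaimage <- function(path, unit = c("HU", "normalized_0_255")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed MetaImage header line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  hdr <- setNames(vals, keys)

  need <- function(key) {
    if (!key %in% names(hdr)) stop("MetaImage header missing required key: ", key)
    hdr[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L)) stop("MetaImage header key NDims: only 3 supported, got ", ndims)
  dimsize <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing_xyz <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  if (length(dimsize) != 3L || anyNA(dimsize))
    stop("MetaImage header key DimSize: expected 3 integers")
  if (length(spacing_xyz) != 3L || anyNA(spacing_xyz))
    stop("MetaImage header key ElementSpacing: expected 3 numbers")
  origin <- if ("Offset" %in% names(hdr)) {
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  } else c(0, 0, 0)
  type <- need("ElementType")
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop("MetaImage header key ElementDataFile: LOCAL (embedded) data not supported")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)

  n <- prod(dimsize)
  reader <- switch(type,
    MET_DOUBLE = function(con) readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = function(con) readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT  = function(con) readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    MET_USHORT = function(con) readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    MET_UCHAR  = function(con) readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    MET_CHAR   = function(con) readBin(con, "integer", n, size = 1, signed = TRUE, endian = "little"),
    stop("MetaImage header key ElementType: unsupported type ", type)
  )
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- as.numeric(reader(con))
  if (length(vals) != n) stop("raw file shorter than DimSize implies: ", rawpath)
  vox_xyz <- array(vals, dim = dimsize)          # (x,y,z), x fastest
  volume(aperm(vox_xyz, c(3, 2, 1)),             # -> (z,y,x)
         spacing = rev(spacing_xyz), origin = origin, unit = unit)
}

#' @rdname read_metaimage
#' @param vol a [volume()] to write.
#' @param element_type on-disk scalar type: `"MET_DOUBLE"` (lossless,
#'   default), `"MET_FLOAT"`, `"MET_SHORT"` or `"MET_UCHAR"`.
#' @export
write_metaimage <- function(vol, path,
                            element_type = c("MET_DOUBLE", "MET_FLOAT",
                                             "MET_SHORT", "MET_UCHAR")) {
  stopifnot(inherits(vol, "volume"))
  element_type <- match.arg(element_type)
  d_zyx <- dim(vol$voxels)
  rawfile <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(rawfile, basename(path))) rawfile <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, digits = 17, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", paste(format(rev(vol$spacing), digits = 17, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(rev(d_zyx), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", rawfile)
  )
  writeLines(hdr, path)
  vox_xyz <- aperm(vol$voxels, c(3, 2, 1))
  con <- file(file.path(dirname(path), rawfile), "wb")
  on.exit(close(con))
  v <- as.numeric(vox_xyz)
  switch(element_type,
    MET_DOUBLE = writeBin(v, con, size = 8, endian = "little"),
    MET_FLOAT  = writeBin(v, con, size = 4, endian = "little"),
    MET_SHORT  = writeBin(as.integer(round(v)), con, size = 2, endian = "little"),
    MET_UCHAR  = writeBin(as.integer(round(pmin(pmax(v, 0), 255))), con, size = 1,
                          endian = "little")
  )
  invisible(path)
}
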