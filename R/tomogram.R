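#' Construct a refractive-index tomogram
#'
#' A tomogram is a 3D grid of dimensionless refractive-index (RI) values
#' indexed `(z, y, x)` together with its anisotropic voxel pitch in
#' micrometres and the z index of the culture-substrate surface. RI in live
#' cultures spans roughly 1.33 (medium) to 1.42 (lipid-rich inclusions);
#' values outside `[1.30, 1.50]` are treated as reconstruction artefacts.
#'
#' @param ri numeric 3D array of RI values, dimensions `(nz, ny, nx)`.
#' @param pitch numeric length-3 vector `(dz, dy, dx)` in micrometres.
#' @param substrate_z 1-based z index of the substrate surface slice.
#' @param id character identifier.
#' @param on_range what to do when RI values fall outside `[1.30, 1.50]`:
#'   `"warn"` (default) or `"error"`.
#' @return An object of class `tomogram` with fields `ri`, `pitch`,
#'   `substrate_z`, `id`.
#' @export
tomogram <- function(ri, pitch = ht_default_pitch(), substrate_z = 1L,
                     id = "tomogram", on_range = c("warn", "error")) {
  on_range <- match.arg(on_range)
  if (!is.array(ri) || length(dim(ri)) != 3L)
    stop("`ri` must be a 3D array (z, y, x)")
  if (!all(is.finite(ri))) stop("RI values must all be finite")
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(pitch <= 0))
    stop("`pitch` must be three positive values (dz, dy, dx) in um")
  substrate_z <- as.integer(substrate_z)
  if (!is.na(substrate_z) && (substrate_z < 1L || substrate_z > dim(ri)[1]))
    stop("`substrate_z` out of z range")
  rng <- range(ri)
  if (rng[1] < 1.30 || rng[2] > 1.50) {
    msg <- sprintf("RI values outside [1.30, 1.50] (range %.4f-%.4f)",
                   rng[1], rng[2])
    if (on_range == "error") stop(msg) else warning(msg)
  }
  structure(list(ri = ri, pitch = pitch, substrate_z = substrate_z,
                 id = as.character(id)),
            class = "tomogram")
}

#' Default voxel pitch (um)
#'
#' Lateral pitch 0.3109 um maps a 79.6-um evaluation patch to 256 px, and
#' axial pitch 0.9496 um makes the 11.4-um vertical crop an even 12 slices;
#' both are configurable on every entry point.
#' @return numeric `(dz, dy, dx)` in micrometres.
#' @export
ht_default_pitch <- function() c(0.9496, 0.3109, 0.3109)

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf("<tomogram '%s'> %d x %d x %d voxels (z,y,x)\n", x$id,
              d[1], d[2], d[3]))
  cat(sprintf("  pitch (dz,dy,dx): %.4f x %.4f x %.4f um, substrate_z = %s\n",
              x$pitch[1], x$pitch[2], x$pitch[3], as.character(x$substrate_z)))
  cat(sprintf("  RI range: %.4f - %.4f\n", min(x$ri), max(x$ri)))
  invisible(x)
}

#' Construct a 2D map aligned to a tomogram's horizontal grid
#'
#' @param values numeric or logical matrix indexed `(y, x)`.
#' @param pitch `(dy, dx)` in micrometres.
#' @param kind one of `"mip"`, `"thickness"`, `"dry_mass"`, `"pundiff"`,
#'   `"saliency"`, `"lipid_presence"`, `"gap_presence"`, `"mask"`.
#' @return object of class `map2d`.
#' @export
map2d <- function(values, pitch, kind = "mip") {
  stopifnot(is.matrix(values), length(pitch) == 2L, all(pitch > 0))
  kinds <- c("mip", "thickness", "dry_mass", "pundiff", "saliency",
             "lipid_presence", "gap_presence", "mask")
  kind <- match.arg(kind, kinds)
  structure(list(values = values, pitch = as.numeric(pitch), kind = kind),
            class = "map2d")
}

#' @export
print.map2d <- function(x, ...) {
  cat(sprintf("<map2d kind='%s'> %d x %d px at %.4f x %.4f um\n", x$kind,
              nrow(x$values), ncol(x$values), x$pitch[1], x$pitch[2]))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

# Minimal uncompressed multi-page 32-bit float TIFF writer (SampleFormat =
# IEEE float, one strip per page). The tiff package reads float TIFFs via
# libtiff but can only write integer samples, which silently quantizes RI
# values; this writer keeps storage exact at 32-bit precision.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wb4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  writeBin(charToRaw("II"), con); wb2(42L)
  n <- length(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  nentries <- 10L
  ifd_size <- 2L + nentries * 12L + 4L
  data_size <- 4L * H * W
  ifd_off <- 8 + (seq_len(n) - 1) * (ifd_size + data_size)
  data_off <- ifd_off + ifd_size
  wb4(ifd_off[1])
  entry <- function(tag, type, count, value) {
    wb2(tag); wb2(type); wb4(count); wb4(value)
  }
  for (p in seq_len(n)) {
    wb2(nentries)
    entry(256, 4, 1, W)             # ImageWidth
    entry(257, 4, 1, H)             # ImageLength
    entry(258, 3, 1, 32)            # BitsPerSample
    entry(259, 3, 1, 1)             # Compression: none
    entry(262, 3, 1, 1)             # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[p])   # StripOffsets
    entry(277, 3, 1, 1)             # SamplesPerPixel
    entry(278, 4, 1, H)             # RowsPerStrip
    entry(279, 4, 1, data_size)     # StripByteCounts
    entry(339, 3, 1, 3)             # SampleFormat: IEEE float
    wb4(if (p < n) ifd_off[p + 1] else 0L)
    writeBin(as.vector(t(pages[[p]])), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a tomogram to disk
#'
#' Values are stored as multi-page 32-bit float TIFF (one page per z slice)
#' with a JSON sidecar (`<path>.json`) holding pitch, substrate index, id
#' and the storage scale.
#'
#' @param t a [tomogram].
#' @param path destination file path.
#' @param format storage format; only `"tiff"` is available.
#' @param overwrite overwrite an existing file? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(t, path, format = c("tiff", "hdf5"),
                           overwrite = TRUE) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 storage is not available in this build; use format = 'tiff'")
  stopifnot(inherits(t, "tomogram"))
  if (!overwrite && file.exists(path))
    stop("file exists and overwrite = FALSE: ", path)
  nz <- dim(t$ri)[1]
  pages <- lapply(seq_len(nz), function(z) t$ri[z, , ])
  ok <- try(write_float_tiff(pages, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to ", path)
  meta <- list(pitch_um = t$pitch, substrate_z = t$substrate_z - 1L,
               id = t$id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a tomogram from disk
#'
#' Reads a multi-page float TIFF written by [write_tomogram()] (or any
#' multi-page TIFF volume). Pitch and substrate index come from the JSON
#' sidecar when present, otherwise from the arguments.
#'
#' @param path file path.
#' @param format only `"tiff"` is available.
#' @param pitch fallback `(dz, dy, dx)` in um when no sidecar exists.
#' @param substrate_z fallback substrate slice index (1-based).
#' @param on_range passed to [tomogram()].
#' @return a [tomogram].
#' @export
read_tomogram <- function(path, format = c("tiff", "hdf5"),
                          pitch = ht_default_pitch(), substrate_z = 1L,
                          on_range = "warn") {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 storage is not available in this build; use format = 'tiff'")
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("TIFF pages do not decode to single-channel 2D slices")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have inconsistent shapes")
  scale <- 1
  id <- sub("\\.[^.]*$", "", basename(path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$pitch_um)) pitch <- as.numeric(meta$pitch_um)
    if (!is.null(meta$substrate_z)) substrate_z <- meta$substrate_z + 1L
    if (!is.null(meta$id)) id <- meta$id
    if (!is.null(meta$value_scale)) scale <- meta$value_scale
  }
  nz <- length(pages)
  ri <- array(0, c(nz, dims[1, 1], dims[2, 1]))
  for (z in seq_len(nz)) ri[z, , ] <- pages[[z]] * scale
  storage.mode(ri) <- "double"
  tomogram(ri, pitch = pitch, substrate_z = substrate_z, id = id,
           on_range = on_range)
}

#' Maximum-intensity projection along z
#'
#' Per-(y, x) maximum RI over all z slices; the footprint segmentation
#' thresholds this projection.
#'
#' @param t a [tomogram].
#' @param from_z optional first z slice (1-based) to include, e.g. the
#'   substrate slice; default 1 (whole volume).
#' @return a [map2d] of kind `"mip"`.
#' @export
mip_z <- function(t, from_z = 1L) {
  stopifnot(inherits(t, "tomogram"))
  nz <- dim(t$ri)[1]
  from_z <- max(1L, as.integer(from_z))
  if (from_z > nz) stop("from_z beyond volume depth")
  vals <- t$ri[from_z, , ]
  if (from_z < nz)
    for (z in (from_z + 1L):nz) vals <- pmax(vals, t$ri[z, , ])
  map2d(vals, pitch = t$pitch[2:3], kind = "mip")
}

#' Serialize a binary mask as an 8-bit TIFF
#' @param mask logical matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}
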