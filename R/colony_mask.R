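#' Rasterized disk structuring element of physical radius
#'
#' Pixel (i, j) belongs to the kernel when the center-to-center distance
#' `sqrt((i*dy)^2 + (j*dx)^2)` does not exceed `r`; a 1-um kernel at
#' 0.3109-um pitch is a 7x7 neighbourhood disk.
#'
#' @param r radius in um.
#' @param pitch `(dy, dx)` in um.
#' @return 0/1 numeric matrix with odd dimensions.
#' @export
disk_kernel <- function(r, pitch) {
  ny <- floor(r / pitch[1]); nx <- floor(r / pitch[2])
  iy <- (-ny):ny; ix <- (-nx):nx
  k <- outer((iy * pitch[1])^2, (ix * pitch[2])^2, "+") <= r^2
  storage.mode(k) <- "double"
  k
}

# binary dilation/erosion with the region outside the image treated as
# background (EBImage treats out-of-image pixels as foreground when
# eroding, which would stop footprints from eroding at the field edge)
morph2d <- function(m, kern, op = c("dilate", "erode")) {
  op <- match.arg(op)
  p <- max((dim(kern) - 1L) %/% 2L)
  mp <- matrix(0, nrow(m) + 2L * p, ncol(m) + 2L * p)
  mp[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m))] <- as.numeric(m)
  out <- if (op == "dilate") EBImage::dilate(mp, kern) else
    EBImage::erode(mp, kern)
  out[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m)), drop = FALSE] > 0.5
}

close_with_fill <- function(m, kern, fill = c("within", "after", "none")) {
  fill <- match.arg(fill)
  d <- morph2d(m, kern, "dilate")
  if (fill == "within")
    d <- EBImage::fillHull(matrix(as.numeric(d), nrow(d))) > 0.5
  e <- morph2d(d, kern, "erode")
  if (fill == "after")
    e <- EBImage::fillHull(matrix(as.numeric(e), nrow(e))) > 0.5
  e
}

#' Segment the colony footprint from the z-projection
#'
#' Thresholds the maximum-intensity projection (computed from the substrate
#' slice upward) at `thresh`, then applies two serial morphological
#' closings with disk kernels of radii `r1` and `r2`; inside each closing,
#' enclosed background regions are filled between the dilation and the
#' erosion, so interior low-RI pockets (intercellular gaps, thin spots)
#' belong to the footprint.
#'
#' @param t a [tomogram]; slices below `substrate_z` are excluded before
#'   projection.
#' @param thresh RI threshold on the projection (strictly above).
#' @param r1,r2 closing-kernel radii in um.
#' @param fill `"within"` (default; fill between dilation and erosion of
#'   each closing), `"after"` (plain closing, then fill), or `"none"`.
#' @param largest_only keep only the largest connected component?
#' @return a logical-valued [map2d] of kind `"mask"`.
#' @export
segment_colony_2d <- function(t, thresh = 1.342, r1 = 1, r2 = 2,
                              fill = "within", largest_only = FALSE) {
  stopifnot(inherits(t, "tomogram"))
  sz <- locate_substrate(t)
  mp <- mip_z(t, from_z = sz)
  m <- mp$values > thresh
  if (!any(m)) {
    warning("threshold mask is empty; returning empty footprint")
    return(map2d(m, pitch = t$pitch[2:3], kind = "mask"))
  }
  m <- close_with_fill(m, disk_kernel(r1, t$pitch[2:3]), fill)
  m <- close_with_fill(m, disk_kernel(r2, t$pitch[2:3]), fill)
  if (largest_only) {
    lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m)))
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0])
      m <- lab == which.max(sizes)
    }
  }
  map2d(m, pitch = t$pitch[2:3], kind = "mask")
}

#' 3D colony occupancy mask
#'
#' A voxel belongs to the colony iff its RI strictly exceeds `thresh3d`,
#' its (y, x) column lies in the 2D footprint, and it sits at or above the
#' substrate slice.
#'
#' @param t a [tomogram].
#' @param mask2d footprint [map2d] (or logical matrix) from
#'   [segment_colony_2d()].
#' @param thresh3d RI threshold (strict `>`; a voxel at exactly 1.3400 is
#'   excluded).
#' @return logical 3D array aligned to `t$ri`.
#' @export
segment_colony_3d <- function(t, mask2d, thresh3d = 1.3400) {
  stopifnot(inherits(t, "tomogram"))
  m2 <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  if (!all(dim(m2) == dim(t$ri)[2:3]))
    stop("mask2d shape does not match the tomogram horizontally")
  sz <- locate_substrate(t)
  out <- array(FALSE, dim(t$ri))
  for (z in seq_len(dim(t$ri)[1])) {
    if (z < sz) next
    out[z, , ] <- (t$ri[z, , ] > thresh3d) & m2
  }
  out
}

#' Locate the substrate slice
#'
#' Returns the stored `substrate_z` when present; otherwise estimates it as
#' the lowest z slice whose fraction of voxels above RI 1.3400 first
#' exceeds `occupancy_frac` of the in-plane area.
#'
#' @param t a [tomogram].
#' @param occupancy_frac minimum occupied in-plane fraction (default 0.5 %).
#' @param thresh RI occupancy threshold.
#' @return 1-based z index.
#' @export
locate_substrate <- function(t, occupancy_frac = 0.005, thresh = 1.3400) {
  stopifnot(inherits(t, "tomogram"))
  if (!is.na(t$substrate_z)) return(t$substrate_z)
  for (z in seq_len(dim(t$ri)[1]))
    if (mean(t$ri[z, , ] > thresh) > occupancy_frac) return(z)
  stop("no colony signal: no z slice exceeds the occupancy fraction")
}

erode_mask <- function(m, r_um, pitch)
  morph2d(m, disk_kernel(r_um, pitch), "erode")

dilate_mask <- function(m, r_um, pitch)
  morph2d(m, disk_kernel(r_um, pitch), "dilate")

#' Footprint, occupancy and boundary masks of a colony
#'
#' Bundles [segment_colony_2d()], [segment_colony_3d()] and the 1-pixel
#' boundary contour (footprint minus its 1-pixel erosion).
#'
#' @param t a [tomogram].
#' @param thresh,r1,r2,fill,largest_only forwarded to
#'   [segment_colony_2d()].
#' @param thresh3d forwarded to [segment_colony_3d()].
#' @return object of class `colony_masks` with `mask2d`, `mask3d`,
#'   `boundary2d`, `pitch`, `substrate_z`.
#' @export
colony_masks <- function(t, thresh = 1.342, r1 = 1, r2 = 2,
                         fill = "within", largest_only = FALSE,
                         thresh3d = 1.3400) {
  m2 <- segment_colony_2d(t, thresh, r1, r2, fill, largest_only)
  m3 <- segment_colony_3d(t, m2, thresh3d)
  b <- m2$values & !erode_1px(m2$values)
  structure(list(mask2d = m2$values, mask3d = m3, boundary2d = b,
                 pitch = t$pitch, substrate_z = locate_substrate(t)),
            class = "colony_masks")
}

erode_1px <- function(m) morph2d(m, matrix(1, 3, 3), "erode")
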