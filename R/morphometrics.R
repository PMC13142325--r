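#' Names of the 31 colony properties
#'
#' Fifteen scalar descriptors plus four spatial-moment summaries (spread,
#' skewness, kurtosis, centroid displacement) for each of four spatial
#' maps: thickness, areal dry mass, lipid presence and gap presence.
#' @return character vector of length 31.
#' @export
property_names <- function() {
  scalars <- c("area", "volume", "mean_ri", "std_ri", "total_dry_mass",
               "mean_thickness", "std_thickness", "aspect_ratio",
               "curvature", "roundness", "solidity", "eccentricity",
               "boundary_ri_contrast", "lipid_volume", "gap_area_ratio")
  maps <- c("thickness", "dry_mass", "lipid", "gap")
  moments <- c("spread", "skewness", "kurtosis", "centroid_disp")
  c(scalars, as.vector(t(outer(maps, moments, paste, sep = "_"))))
}

#' Column-wise thickness map
#'
#' Thickness of each (y, x) column is the number of occupied voxels times
#' the axial pitch.
#'
#' @param mask3d logical occupancy array `(z, y, x)`.
#' @param pitch `(dz, dy, dx)` um.
#' @return a [map2d] of kind `"thickness"` (um).
#' @export
thickness_map <- function(mask3d, pitch = ht_default_pitch()) {
  tm <- colSums(mask3d) * pitch[1]
  map2d(tm, pitch = pitch[2:3], kind = "thickness")
}

#' Thickness statistics inside an inset footprint
#'
#' Statistics are taken at least `inset` um inwards from the footprint
#' boundary to reduce bias from colony size and edge shape.
#'
#' @param tm thickness [map2d].
#' @param mask2d footprint mask (logical matrix or [map2d]).
#' @param inset boundary inset in um (default 5).
#' @return list `(mean, sd)` in um.
#' @export
thickness_stats <- function(tm, mask2d, inset = 5) {
  v <- if (inherits(tm, "map2d")) tm$values else tm
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  pitch <- if (inherits(tm, "map2d")) tm$pitch else ht_default_pitch()[2:3]
  mi <- erode_mask(m, inset, pitch)
  if (!any(mi)) stop("colony too small for inset")
  x <- v[mi]
  list(mean = mean(x), sd = stats::sd(x))
}

# Upper-surface height per column as occupied-voxel count times dz: equal
# to the highest true voxel for solid columns, but robust to isolated
# speckle voxels above the colony surface.
top_surface_heights <- function(mask3d, substrate_z = 1L, dz = 1) {
  cnt <- colSums(mask3d)
  h <- cnt * dz
  h[cnt == 0L] <- NA_real_
  h
}

#' Colony-surface curvature by algebraic sphere fitting
#'
#' Collects the top-surface voxel of each column at least `inset` um inside
#' the footprint boundary and fits a sphere by linear least squares
#' (Coope's algebraic fit). Curvature is the reciprocal fitted radius,
#' positive for a dome (sphere centre below the surface) and negative for
#' a bowl; near-planar surfaces are capped at a radius of 1e5 um.
#'
#' @param mask3d occupancy array.
#' @param mask2d footprint mask.
#' @param pitch `(dz, dy, dx)` um.
#' @param inset boundary inset, um.
#' @param substrate_z substrate slice (heights are measured from it; the
#'   curvature is offset-invariant).
#' @param refine polish the algebraic seed with a geometric
#'   (orthogonal-distance) Gauss-Newton fit? The algebraic fit is biased
#'   toward small radii for shallow voxelized surfaces; the geometric fit
#'   removes most of that bias. Default `TRUE`.
#' @return curvature in 1/um.
#' @export
fit_sphere_curvature <- function(mask3d, mask2d, pitch = ht_default_pitch(),
                                 inset = 5, substrate_z = 1L,
                                 refine = TRUE) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  mi <- erode_mask(m, inset, pitch[2:3])
  h <- top_surface_heights(mask3d, substrate_z, pitch[1])
  sel <- which(mi & !is.na(h), arr.ind = TRUE)
  if (nrow(sel) < 4L) stop("fewer than 4 surface points for the sphere fit")
  y <- sel[, 1] * pitch[2]; x <- sel[, 2] * pitch[3]
  z <- h[sel]
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  rhs <- x^2 + y^2 + z^2
  qr_A <- qr(A)
  if (qr_A$rank < 4L) {
    # an exactly flat surface makes the z column collinear with the
    # intercept: the planar limit, reported as zero curvature
    if (stats::sd(z) < 1e-9) return(0)
    stop("surface points are coplanar/degenerate")
  }
  cf <- qr.coef(qr_A, rhs)
  R2 <- cf[4] + cf[1]^2 + cf[2]^2 + cf[3]^2
  if (!is.finite(R2) || R2 <= 0) return(0)
  ctr <- cf[1:3]
  R <- sqrt(R2)
  if (refine && R < 1e5) {
    # geometric (orthogonal-distance) Gauss-Newton polish of the algebraic
    # seed; the algebraic fit underestimates shallow radii under the
    # axial quantization noise of voxelized surfaces
    P <- cbind(x, y, z)
    for (it in seq_len(30L)) {
      dvec <- sqrt(rowSums(sweep(P, 2, ctr)^2))
      r_cur <- mean(dvec)
      res <- dvec - r_cur
      J <- -sweep(P, 2, ctr) / pmax(dvec, 1e-9)
      Jc <- sweep(J, 2, colMeans(J))
      step <- tryCatch(qr.coef(qr(Jc), -res), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      ctr <- ctr + step
      if (sqrt(sum(step^2)) < 1e-6 * max(r_cur, 1)) break
    }
    R <- mean(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  }
  R <- min(R, 1e5)
  sgn <- if (ctr[3] < mean(z)) 1 else -1
  sgn / R
}

# connected components of a sparse voxel index set (6-connectivity)
components_3d <- function(idx, dims) {
  if (!length(idx)) return(list())
  nz <- dims[1]; ny <- dims[2]
  ord <- sort(idx)
  pos <- seq_along(ord)
  edges <- integer(0)
  # neighbours along z: linear index +1 unless at slab boundary
  zc <- ((ord - 1L) %% nz) + 1L
  yc <- (((ord - 1L) %/% nz) %% ny) + 1L
  nb_list <- list(
    ifelse(zc < nz, ord + 1L, NA_integer_),
    ifelse(yc < ny, ord + nz, NA_integer_),
    ord + nz * ny)
  for (nb in nb_list) {
    j <- match(nb, ord)
    ok <- !is.na(j)
    if (any(ok)) edges <- c(edges, rbind(pos[ok], j[ok]))
  }
  g <- igraph::make_empty_graph(n = length(ord), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  split(ord, comp$membership)
}

feret_horizontal <- function(idx, dims, pitch) {
  nz <- dims[1]; ny <- dims[2]
  yc <- (((idx - 1L) %/% nz) %% ny) + 1L
  xc <- ((idx - 1L) %/% (nz * ny)) + 1L
  pts <- unique(cbind(yc * pitch[2], xc * pitch[3]))
  if (nrow(pts) == 1L) return(0)
  hp <- grDevices::chull(pts)
  pts <- pts[hp, , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  max(d)
}

#' Detect lipid droplets
#'
#' Connected high-RI components (RI strictly above `lo`) inside the colony
#' volume are lipid candidates; a component whose maximum horizontal Feret
#' diameter exceeds `width` um is kept only if its peak RI reaches `hi`
#' (dense non-lipid organelles are excluded by this size rule).
#'
#' @param t a [tomogram].
#' @param mask3d occupancy array.
#' @param lo candidate RI threshold (default 1.3800, strict).
#' @param hi peak-RI rescue threshold for wide components (default 1.4000).
#' @param width Feret-width cutoff in um (default 3).
#' @return list: `voxels` (linear indices of retained voxels),
#'   `lipid_volume` (um^3), `presence2d` (logical y-x map of columns
#'   containing retained voxels).
#' @export
detect_lipid <- function(t, mask3d, lo = 1.3800, hi = 1.4000, width = 3) {
  stopifnot(inherits(t, "tomogram"))
  dims <- dim(t$ri)
  cand <- which((t$ri > lo) & mask3d)
  comps <- components_3d(cand, dims)
  keep <- integer(0)
  for (cp in comps) {
    f <- feret_horizontal(cp, dims, t$pitch)
    if (f <= width || max(t$ri[cp]) >= hi) keep <- c(keep, cp)
  }
  voxvol <- prod(t$pitch)
  pres <- matrix(FALSE, dims[2], dims[3])
  if (length(keep)) {
    nz <- dims[1]; ny <- dims[2]
    yc <- (((keep - 1L) %/% nz) %% ny) + 1L
    xc <- ((keep - 1L) %/% (nz * ny)) + 1L
    pres[cbind(yc, xc)] <- TRUE
  }
  list(voxels = keep, lipid_volume = length(keep) * voxvol,
       presence2d = pres)
}

#' Detect intercellular gaps
#'
#' Gap candidates are connected components of low-RI pixels (projection
#' value at or below `thresh`) inside the footprint. A component with at
#' least `frac` of its area within `prox` um of the footprint boundary is
#' discarded as a boundary artefact.
#'
#' @param t a [tomogram].
#' @param mask2d footprint mask.
#' @param thresh RI threshold on the z-projection (inclusive `<=`).
#' @param prox boundary proximity in um.
#' @param frac boundary-proximal area fraction at or above which a
#'   component is dropped.
#' @return list: `gap_mask` (logical), `gap_area_ratio` (retained gap area
#'   over footprint area).
#' @export
detect_gaps <- function(t, mask2d, thresh = 1.3400, prox = 5, frac = 0.25) {
  stopifnot(inherits(t, "tomogram"))
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  sz <- locate_substrate(t)
  mp <- mip_z(t, from_z = sz)$values
  cand <- (mp <= thresh) & m
  gap <- matrix(FALSE, nrow(m), ncol(m))
  ratio <- 0
  if (any(cand)) {
    dmap <- EBImage::distmap(matrix(as.numeric(m), nrow(m))) * t$pitch[3]
    near <- dmap <= prox
    lab <- EBImage::bwlabel(matrix(as.numeric(cand), nrow(m)))
    for (k in seq_len(max(lab))) {
      px <- lab == k
      if (mean(near[px]) >= frac) next
      gap <- gap | px
    }
    ratio <- sum(gap) / max(sum(m), 1L)
  }
  list(gap_mask = gap, gap_area_ratio = ratio)
}

# Chain-code perimeter with the Vossepoel-Smeulders corner correction
# (0.948 per axial step, 1.340 per diagonal step): the raw staircase
# polygon overestimates smooth boundaries by ~5 %, which would bias the
# isoperimetric roundness of near-circular colonies.
mask_contour_perimeter <- function(m, pitch) {
  oc <- EBImage::ocontour(matrix(as.numeric(m), nrow(m)))
  px <- mean(pitch)
  per <- 0
  for (ct in oc) {
    if (nrow(ct) < 2L) next
    d <- abs(diff(rbind(ct, ct[1, , drop = FALSE])))
    steps <- d[, 1] + d[, 2]
    n_ax <- sum(steps == 1)
    n_di <- sum(steps == 2 & d[, 1] == 1)
    rest <- steps > 2 | (steps == 2 & d[, 1] != 1)
    per <- per + (0.948 * n_ax + 1.340 * n_di) * px +
      sum(sqrt(d[rest, 1]^2 + d[rest, 2]^2)) * px
  }
  per
}

poly_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' 2D shape descriptors of the footprint
#'
#' Roundness is the isoperimetric ratio `4*pi*A/P^2` with `P` the polygonal
#' contour perimeter; solidity is the area ratio of mask to convex hull;
#' eccentricity comes from the second-moment ellipse fit,
#' `e = sqrt(1 - b^2/a^2)`.
#'
#' @param mask2d footprint mask (largest component used when several).
#' @param pitch `(dy, dx)` um.
#' @return list `(roundness, solidity, eccentricity, area,
#'   major_axis_um, minor_axis_um)`; area in um^2.
#' @export
shape_descriptors <- function(mask2d, pitch = ht_default_pitch()[2:3]) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  if (sum(m) < 16L) stop("mask too small for shape descriptors")
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m)))
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  A <- sum(m) * pitch[1] * pitch[2]
  P <- mask_contour_perimeter(m, pitch)
  roundness <- min(4 * pi * A / P^2, 1)
  ij <- which(m, arr.ind = TRUE)
  pts <- cbind(ij[, 1] * pitch[1], ij[, 2] * pitch[2])
  # hull over pixel corners: a centre-point hull underestimates the pixel
  # set by half a pixel all around, pinning solidity at exactly 1
  corners <- rbind(
    cbind(pts[, 1] - pitch[1] / 2, pts[, 2] - pitch[2] / 2),
    cbind(pts[, 1] - pitch[1] / 2, pts[, 2] + pitch[2] / 2),
    cbind(pts[, 1] + pitch[1] / 2, pts[, 2] - pitch[2] / 2),
    cbind(pts[, 1] + pitch[1] / 2, pts[, 2] + pitch[2] / 2))
  hp <- grDevices::chull(corners)
  A_hull <- max(poly_area(corners[hp, , drop = FALSE]), A)
  solidity <- min(A / A_hull, 1)
  mu <- colMeans(pts)
  cy <- pts[, 1] - mu[1]; cx <- pts[, 2] - mu[2]
  m20 <- mean(cy^2); m02 <- mean(cx^2); m11 <- mean(cy * cx)
  tr <- m20 + m02
  dt <- sqrt((m20 - m02)^2 + 4 * m11^2)
  lam1 <- (tr + dt) / 2; lam2 <- (tr - dt) / 2
  ecc <- if (lam1 <= 0) 0 else sqrt(max(0, 1 - lam2 / lam1))
  list(roundness = roundness, solidity = solidity, eccentricity = ecc,
       area = A, major_axis_um = 4 * sqrt(lam1),
       minor_axis_um = 4 * sqrt(max(lam2, 0)))
}

#' RI contrast across the colony boundary
#'
#' Difference between the mean projection RI over the band `band` um
#' inwards of the boundary and the band `band` um outwards.
#'
#' @param t a [tomogram].
#' @param mask2d footprint mask.
#' @param band band width in um (default 2).
#' @return contrast in RI units.
#' @export
boundary_ri_contrast <- function(t, mask2d, band = 2) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  sz <- locate_substrate(t)
  mp <- mip_z(t, from_z = sz)$values
  inner <- m & !erode_mask(m, band, t$pitch[2:3])
  outer <- dilate_mask(m, band, t$pitch[2:3]) & !m
  if (!any(inner) || !any(outer)) stop("empty boundary band")
  mean(mp[inner]) - mean(mp[outer])
}

#' Dry mass from the RI excess
#'
#' Voxel dry mass is `(RI - n_medium) / alpha` times the voxel volume,
#' with `alpha` the specific refractive increment (0.185 um^3/pg);
#' negative increments are clipped to zero. Returns the areal density map,
#' the total mass and the z-resolved profile, plus a helper evaluation of
#' arbitrary z windows above the substrate.
#'
#' @param t a [tomogram].
#' @param mask3d occupancy array.
#' @param n_medium medium RI.
#' @param alpha specific refractive increment, um^3/pg.
#' @param z_windows optional list of `c(lo, hi)` um windows above the
#'   substrate (slice centres in `[lo, hi)`) to aggregate, e.g. basal
#'   `c(1.899, 3.798)` and apical `c(9.496, 11.395)`.
#' @return list: `areal` ([map2d], pg/um^2), `total` (pg), `z_profile`
#'   (pg per slice), `window_mass` (named pg values when `z_windows`
#'   given).
#' @export
dry_mass <- function(t, mask3d, n_medium = 1.337, alpha = 0.185,
                     z_windows = NULL) {
  stopifnot(inherits(t, "tomogram"))
  if (alpha <= 0) stop("alpha must be positive")
  dims <- dim(t$ri)
  voxvol <- prod(t$pitch)
  pixarea <- t$pitch[2] * t$pitch[3]
  sz <- locate_substrate(t)
  areal <- matrix(0, dims[2], dims[3])
  zprof <- numeric(dims[1])
  for (z in seq_len(dims[1])) {
    sl <- pmax(t$ri[z, , ] - n_medium, 0) / alpha * voxvol
    sl[!mask3d[z, , ]] <- 0
    areal <- areal + sl
    zprof[z] <- sum(sl)
  }
  out <- list(areal = map2d(areal / pixarea, pitch = t$pitch[2:3],
                            kind = "dry_mass"),
              total = sum(zprof), z_profile = zprof)
  if (!is.null(z_windows)) {
    zc <- (seq_len(dims[1]) - sz + 0.5) * t$pitch[1]
    out$window_mass <- vapply(z_windows, function(w)
      sum(zprof[zc >= w[1] & zc < w[2]]), numeric(1))
    if (!is.null(names(z_windows))) names(out$window_mass) <- names(z_windows)
  }
  out
}

#' Spatial moments of a non-negative map over a footprint
#'
#' The map is treated as a 2D weight density over the footprint. With `r`
#' the distance of each pixel from the weighted centroid: spread is
#' `sqrt(E[r^2])` normalized by the footprint's equivalent radius,
#' skewness and kurtosis are the standardized third and fourth moments of
#' `r`, and the centroid displacement is the distance between weighted and
#' unweighted centroids, again normalized by the equivalent radius.
#'
#' @param m [map2d] or numeric matrix (negative values clipped to 0).
#' @param mask2d footprint mask.
#' @param pitch `(dy, dx)` um.
#' @return named numeric `(spread, skewness, kurtosis, centroid_disp)`;
#'   all zero (with attribute `degenerate = TRUE`) for an all-zero map.
#' @export
spatial_moments <- function(m, mask2d, pitch = ht_default_pitch()[2:3]) {
  v <- if (inherits(m, "map2d")) m$values else m
  msk <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  if (inherits(m, "map2d")) pitch <- m$pitch
  stopifnot(all(dim(v) == dim(msk)), any(msk))
  ij <- which(msk, arr.ind = TRUE)
  w <- pmax(v[msk], 0)
  py <- ij[, 1] * pitch[1]; px <- ij[, 2] * pitch[2]
  r_eq <- sqrt(sum(msk) * pitch[1] * pitch[2] / pi)
  out <- c(spread = 0, skewness = 0, kurtosis = 0, centroid_disp = 0)
  tot <- sum(w)
  if (tot <= 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cyw <- sum(w * py) / tot; cxw <- sum(w * px) / tot
  r <- sqrt((py - cyw)^2 + (px - cxw)^2)
  out["spread"] <- sqrt(sum(w * r^2) / tot) / r_eq
  mr <- sum(w * r) / tot
  m2 <- sum(w * (r - mr)^2) / tot
  if (m2 > 1e-12) {
    out["skewness"] <- (sum(w * (r - mr)^3) / tot) / m2^1.5
    out["kurtosis"] <- (sum(w * (r - mr)^4) / tot) / m2^2
  }
  cy0 <- mean(py); cx0 <- mean(px)
  out["centroid_disp"] <- sqrt((cyw - cy0)^2 + (cxw - cx0)^2) / r_eq
  out
}

#' Upper-surface profile along the footprint's major axis
#'
#' Samples the top-surface height along the second-moment major axis
#' through the footprint centroid; the traversed arc is rescaled to
#' positions 0 to 1 so profiles of colonies of different sizes are
#' comparable.
#'
#' @param mask3d occupancy array.
#' @param mask2d footprint mask.
#' @param pitch `(dz, dy, dx)` um.
#' @param n_points number of samples.
#' @param substrate_z substrate slice index.
#' @return list: `position` (0..1), `height` (um, 0 outside the colony).
#' @export
surface_profile <- function(mask3d, mask2d, pitch = ht_default_pitch(),
                            n_points = 100L, substrate_z = 1L) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  ij <- which(m, arr.ind = TRUE)
  if (nrow(ij) < 4L) stop("degenerate footprint")
  pts <- cbind(ij[, 1] * pitch[2], ij[, 2] * pitch[3])
  mu <- colMeans(pts)
  cc <- sweep(pts, 2, mu)
  S <- crossprod(cc) / nrow(cc)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[1] < 1e-9) stop("degenerate major axis")
  dir <- ev$vectors[, 1]
  proj <- cc %*% dir
  tmin <- min(proj); tmax <- max(proj)
  if (tmax - tmin < 1e-9) stop("degenerate major axis")
  h <- top_surface_heights(mask3d, substrate_z, pitch[1])
  h[is.na(h)] <- 0
  ts <- seq(tmin, tmax, length.out = n_points)
  height <- vapply(ts, function(tt) {
    p <- mu + tt * dir
    bilinear_at(h, p[1] / pitch[2], p[2] / pitch[3])
  }, numeric(1))
  list(position = (ts - tmin) / (tmax - tmin), height = pmax(height, 0))
}

bilinear_at <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- min(max(y, 1), ny); x <- min(max(x, 1), nx)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- min(y0 + 1, ny); x1 <- min(x0 + 1, nx)
  fy <- y - y0; fx <- x - x0
  img[y0, x0] * (1 - fy) * (1 - fx) + img[y1, x0] * fy * (1 - fx) +
    img[y0, x1] * (1 - fy) * fx + img[y1, x1] * fy * fx
}

#' Quality-control a colony by bounding-box area
#'
#' Colonies whose footprint bounding box is smaller than `min_bbox` um^2
#' are excluded from property extraction (strictly smaller; a box of
#' exactly `min_bbox` passes).
#'
#' @param mask2d footprint mask.
#' @param pitch `(dy, dx)` um.
#' @param min_bbox minimum bounding-box area, um^2 (default 14,250).
#' @return logical.
#' @export
qc_colony <- function(mask2d, pitch = ht_default_pitch()[2:3],
                      min_bbox = 14250) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  if (!any(m)) return(FALSE)
  ij <- which(m, arr.ind = TRUE)
  h <- diff(range(ij[, 1])) + 1L
  w <- diff(range(ij[, 2])) + 1L
  h * pitch[1] * w * pitch[2] >= min_bbox
}

#' Extract the 31-property morphometric vector of one colony
#'
#' Assembles every scalar descriptor and the spatial moments of the four
#' maps. The aspect ratio is the mean thickness over the equivalent
#' footprint diameter (a height-to-width measure that falls as colonies
#' flatten); set `aspect = "planar"` for the in-plane minor/major axis
#' ratio instead.
#'
#' @param t a [tomogram].
#' @param masks a [colony_masks] object.
#' @param inset thickness/curvature boundary inset, um.
#' @param qc apply [qc_colony()] and error when the colony is too small?
#' @param aspect `"height"` (default) or `"planar"`.
#' @param n_medium,alpha dry-mass conversion constants.
#' @return object of class `property_vector`: named numeric of length 31
#'   with attribute `id`.
#' @export
compute_property_vector <- function(t, masks = NULL, inset = 5, qc = TRUE,
                                    aspect = c("height", "planar"),
                                    n_medium = 1.337, alpha = 0.185) {
  aspect <- match.arg(aspect)
  stopifnot(inherits(t, "tomogram"))
  if (is.null(masks)) masks <- colony_masks(t)
  m2 <- masks$mask2d; m3 <- masks$mask3d
  pitch <- t$pitch
  if (qc && !qc_colony(m2, pitch[2:3]))
    stop("colony bounding box below the QC minimum")
  sz <- masks$substrate_z
  tm <- thickness_map(m3, pitch)
  ts <- thickness_stats(tm, m2, inset)
  sd_ <- shape_descriptors(m2, pitch[2:3])
  dm <- dry_mass(t, m3, n_medium = n_medium, alpha = alpha)
  lip <- detect_lipid(t, m3)
  gap <- detect_gaps(t, m2)
  ri_in <- t$ri[m3]
  eq_diam <- 2 * sqrt(sd_$area / pi)
  ar <- if (aspect == "height") ts$mean / eq_diam else
    sd_$minor_axis_um / sd_$major_axis_um
  vals <- c(
    area = sd_$area,
    volume = sum(m3) * prod(pitch),
    mean_ri = mean(ri_in),
    std_ri = stats::sd(ri_in),
    total_dry_mass = dm$total,
    mean_thickness = ts$mean,
    std_thickness = ts$sd,
    aspect_ratio = ar,
    curvature = fit_sphere_curvature(m3, m2, pitch, inset, sz),
    roundness = sd_$roundness,
    solidity = sd_$solidity,
    eccentricity = sd_$eccentricity,
    boundary_ri_contrast = boundary_ri_contrast(t, m2),
    lipid_volume = lip$lipid_volume,
    gap_area_ratio = gap$gap_area_ratio)
  maps <- list(thickness = tm$values,
               dry_mass = dm$areal$values,
               lipid = lip$presence2d * 1.0,
               gap = gap$gap_mask * 1.0)
  for (nm in names(maps)) {
    mm <- spatial_moments(maps[[nm]], m2, pitch[2:3])
    names(mm) <- paste(nm, names(mm), sep = "_")
    vals <- c(vals, mm)
  }
  stopifnot(identical(names(vals), property_names()), all(is.finite(vals)))
  structure(vals, id = t$id, class = c("property_vector", "numeric"))
}

#' @export
print.property_vector <- function(x, ...) {
  cat(sprintf("<property_vector '%s'>\n", attr(x, "id")))
  print(round(unclass(x), 4))
  invisible(x)
}
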