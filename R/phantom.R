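#' Specification of a synthetic colony tomogram
#'
#' Phantoms emulate stitched holotomography volumes of single hPSC colonies:
#' a medium background (RI 1.337), a substrate surface at a fixed z slice, a
#' dome-shaped (undifferentiated) or flattened (differentiating) colony with
#' a smoothly varying cytoplasmic RI field, nucleoli, high-RI lipid
#' droplets, and -- for the differentiating class -- low-RI intercellular
#' gap channels carved through the colony. They are geometric/statistical
#' stand-ins, not light-scattering simulations.
#'
#' @param class_label `"undifferentiated"` or `"differentiating"`.
#' @param grid volume dimensions `(nz, ny, nx)`.
#' @param pitch voxel pitch `(dz, dy, dx)` in um.
#' @param footprint_radius mean footprint radius in um.
#' @param apex_height apex height in um; default drawn from U(12, 18) for
#'   undifferentiated and U(5, 9) for differentiating colonies.
#' @param boundary_sharpness edge-smoothing Gaussian sigma in um; default
#'   drawn from U(0.6, 1.0) (undiff, sharp) or U(1.8, 2.6) (diff, blurred).
#' @param cytoplasm_ri,cytoplasm_sd mean and SD of the smoothed cytoplasmic
#'   RI field (clipped to `[1.345, 1.370]`).
#' @param medium_ri background medium RI.
#' @param n_lipid number of lipid droplets (radius U(0.4, 1.2) um, RI
#'   U(1.395, 1.405)).
#' @param n_nucleoli number of nucleolus spheres (RI 1.372).
#' @param gap_channels number of low-RI gap channels (differentiating only;
#'   default drawn from 2:4). Channels are placed at least 7 um inside the
#'   footprint boundary so the proximity-exclusion rule retains them.
#' @param noise_sd sensor-noise SD in RI units (default 0.001, below the
#'   0.003 margin between the medium RI and the 1.3400 gap rule; see the
#'   methods vignette).
#' @param substrate_z substrate slice index (1-based).
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec including the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("undifferentiated", "differentiating"),
                         grid = c(24L, 480L, 480L),
                         pitch = ht_default_pitch(),
                         footprint_radius = 62,
                         apex_height = NULL,
                         boundary_sharpness = NULL,
                         cytoplasm_ri = 1.355, cytoplasm_sd = 0.004,
                         medium_ri = 1.337,
                         n_lipid = 6L, n_nucleoli = 5L,
                         gap_channels = NULL,
                         noise_sd = 0.001,
                         substrate_z = 3L,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  structure(list(class_label = class_label, grid = as.integer(grid),
                 pitch = as.numeric(pitch),
                 footprint_radius = footprint_radius,
                 apex_height = apex_height,
                 boundary_sharpness = boundary_sharpness,
                 cytoplasm_ri = cytoplasm_ri, cytoplasm_sd = cytoplasm_sd,
                 medium_ri = medium_ri, n_lipid = as.integer(n_lipid),
                 n_nucleoli = as.integer(n_nucleoli),
                 gap_channels = gap_channels, noise_sd = noise_sd,
                 substrate_z = as.integer(substrate_z),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# bilinear upsample of a coarse 3D field to full grid (z linear, yx bilinear)
upsample_field <- function(coarse, dims) {
  cz <- dim(coarse)[1]
  slices <- lapply(seq_len(cz), function(z)
    EBImage::resize(coarse[z, , ], w = dims[2], h = dims[3]))
  out <- array(0, dims)
  zc <- seq(1, cz, length.out = dims[1])
  for (z in seq_len(dims[1])) {
    lo <- floor(zc[z]); hi <- min(lo + 1, cz); w <- zc[z] - lo
    out[z, , ] <- (1 - w) * slices[[lo]] + w * slices[[hi]]
  }
  out
}

gauss_blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0.05) return(m)
  EBImage::gblur(m, sigma = sigma_px)
}

#' Generate one synthetic colony tomogram with ground truth
#'
#' @param spec a [phantom_spec].
#' @return list with elements `tomogram` (a [tomogram]) and `truth` (class
#'   `phantom_truth`): `class_label`, `footprint` (logical y-x matrix),
#'   `thickness` (um matrix), `cap_radius` and `curvature` (1/cap_radius),
#'   `apex_height`, `lipid_index` (linear voxel indices), `lipid_volume`
#'   (um^3), `gap_mask` (logical), `gap_area_ratio`, `substrate_z`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nz <- spec$grid[1]; ny <- spec$grid[2]; nx <- spec$grid[3]
  dz <- spec$pitch[1]; dy <- spec$pitch[2]; dx <- spec$pitch[3]
  undiff <- spec$class_label == "undifferentiated"

  h <- spec$apex_height
  if (is.null(h)) h <- if (undiff) runif(1, 12, 18) else runif(1, 5, 9)
  sig <- spec$boundary_sharpness
  if (is.null(sig)) sig <- if (undiff) runif(1, 0.6, 1.0) else runif(1, 1.8, 2.6)
  ngap <- spec$gap_channels
  if (is.null(ngap)) ngap <- if (undiff) 0L else sample(2:4, 1)
  a0 <- spec$footprint_radius
  if (h >= (nz - spec$substrate_z) * dz - dz)
    stop("apex height does not fit the grid above the substrate")
  if (2 * a0 > 0.92 * min(ny * dy, nx * dx))
    stop("footprint exceeds the grid")

  # physical (um) in-plane coordinates, colony centred with small jitter
  cy <- (ny / 2 + runif(1, -8, 8)) * dy
  cx <- (nx / 2 + runif(1, -8, 8)) * dx
  yy <- matrix((seq_len(ny) - 0.5) * dy, ny, nx)
  xx <- matrix((seq_len(nx) - 0.5) * dx, ny, nx, byrow = TRUE)
  rho <- sqrt((yy - cy)^2 + (xx - cx)^2)
  theta <- atan2(yy - cy, xx - cx)

  # angularly modulated footprint: gentle lobes for domes, protrusive
  # irregular outline for flattened colonies
  amp <- if (undiff) 0.02 else 0.07
  mod <- rep(0, length(theta))
  for (k in 2:5) mod <- mod + runif(1, 0.3, 1) * cos(k * theta + runif(1, 0, 2 * pi))
  a_theta <- a0 * (1 + amp * mod / 2.6)

  # spherical-cap upper surface; cap radius from mean footprint radius
  cap_r <- (a0^2 + h^2) / (2 * h)
  t_rho <- pmax(sqrt(pmax(cap_r^2 - rho^2, 0)) - (cap_r - h), 0)
  height0 <- t_rho * (rho <= a_theta)
  height <- gauss_blur2d(height0, sig / dx)

  footprint <- height > dz / 2
  thickness <- height * footprint

  # gap channels: radially oriented elliptical slots carved full-height,
  # entirely >= 7 um inside the footprint boundary
  gap_mask <- matrix(FALSE, ny, nx)
  placed <- 0L; tries <- 0L
  while (placed < ngap && tries < 200L) {
    tries <- tries + 1L
    rc <- runif(1, 0.30, 0.55) * a0
    th <- runif(1, 0, 2 * pi)
    gy <- cy + rc * sin(th); gx <- cx + rc * cos(th)
    hl <- runif(1, 8, 12); hw <- runif(1, 1.5, 3)
    if (rc + hl + 7 > a0 * 0.98) next
    u <- (yy - gy) * sin(th) + (xx - gx) * cos(th)   # along radial axis
    v <- -(yy - gy) * cos(th) + (xx - gx) * sin(th)
    ell <- (u / hl)^2 + (v / hw)^2 <= 1
    gap_mask <- gap_mask | ell
    placed <- placed + 1L
  }
  gap_mask <- gap_mask & footprint
  thickness[gap_mask] <- 0

  # cytoplasmic RI: smooth random field, clipped
  coarse <- array(rnorm(6 * 48 * 48), c(6, 48, 48))
  field <- upsample_field(coarse, spec$grid)
  field <- spec$cytoplasm_ri + spec$cytoplasm_sd * (field / stats::sd(field))
  field <- pmin(pmax(field, 1.345), 1.370)

  ri <- array(spec$medium_ri, c(nz, ny, nx))
  occ <- array(FALSE, c(nz, ny, nx))
  for (z in seq_len(nz)) {
    zc <- (z - spec$substrate_z + 0.5) * dz
    if (zc < 0) next
    o <- zc < thickness
    occ[z, , ] <- o
    sl <- ri[z, , ]; fl <- field[z, , ]
    sl[o] <- fl[o]
    ri[z, , ] <- sl
  }

  # nucleoli: small spheres of RI 1.372 in the colony interior
  place_spheres <- function(n, rmin, rmax, ri_fun, min_sep = 0) {
    centers <- matrix(numeric(0), 0, 3)
    idx_all <- integer(0); per <- list()
    tries <- 0L
    while (nrow(centers) < n && tries < 50L * n) {
      tries <- tries + 1L
      py <- runif(1, cy - 0.75 * a0, cy + 0.75 * a0)
      px <- runif(1, cx - 0.75 * a0, cx + 0.75 * a0)
      iy <- pmin(pmax(round(py / dy), 1), ny)
      ix <- pmin(pmax(round(px / dx), 1), nx)
      hcol <- thickness[iy, ix]
      r <- runif(1, rmin, rmax)
      if (hcol < 2 * r + 1) next
      if (min_sep > 0 && nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - py)^2 + (centers[, 2] - px)^2) < min_sep))
        next
      pz <- runif(1, r + 0.3, hcol - r - 0.3)
      # voxelize sphere
      zr <- which(abs((seq_len(nz) - spec$substrate_z + 0.5) * dz - pz) <= r + dz)
      yr <- which(abs((seq_len(ny) - 0.5) * dy - py) <= r + dy)
      xr <- which(abs((seq_len(nx) - 0.5) * dx - px) <= r + dx)
      if (!length(zr) || !length(yr) || !length(xr)) next
      gz <- (zr - spec$substrate_z + 0.5) * dz - pz
      gy2 <- (yr - 0.5) * dy - py
      gx2 <- (xr - 0.5) * dx - px
      d2 <- outer(outer(gz^2, gy2^2, "+"), gx2^2, "+")
      sel <- which(d2 <= r^2, arr.ind = TRUE)
      if (!nrow(sel)) next
      lin <- zr[sel[, 1]] + nz * ((yr[sel[, 2]] - 1) + ny * (xr[sel[, 3]] - 1))
      lin <- lin[occ[lin]]             # keep inside the colony only
      if (!length(lin)) next
      centers <- rbind(centers, c(py, px, pz))
      per[[length(per) + 1L]] <- list(idx = lin, val = ri_fun())
      idx_all <- c(idx_all, lin)
    }
    list(centers = centers, per = per, idx = idx_all)
  }

  nuc <- place_spheres(spec$n_nucleoli, 0.8, 1.6, function() 1.372)
  for (p in nuc$per) ri[p$idx] <- p$val
  lip <- place_spheres(spec$n_lipid, 0.4, 1.2,
                       function() runif(1, 1.395, 1.405), min_sep = 3.5)
  for (p in lip$per) ri[p$idx] <- p$val
  lipid_index <- unique(lip$idx)
  voxvol <- dz * dy * dx

  if (spec$noise_sd > 0)
    ri <- ri + rnorm(length(ri), 0, spec$noise_sd)
  ri <- pmin(pmax(ri, 1.301), 1.499)

  t <- tomogram(ri, pitch = spec$pitch, substrate_z = spec$substrate_z,
                id = sprintf("phantom_%s_%d", substr(spec$class_label, 1, 6),
                             spec$seed))
  truth <- structure(list(
    class_label = spec$class_label,
    footprint = footprint,
    thickness = thickness,
    cap_radius = cap_r,
    curvature = 1 / cap_r,
    apex_height = h,
    lipid_index = lipid_index,
    lipid_volume = length(lipid_index) * voxvol,
    gap_mask = gap_mask,
    gap_area_ratio = sum(gap_mask) / max(sum(footprint), 1),
    substrate_z = spec$substrate_z,
    spec = spec), class = "phantom_truth")
  list(tomogram = t, truth = truth)
}

#' Generate a balanced labelled cohort of phantom colonies
#'
#' Per-colony geometry (footprint radius, apex height, boundary sharpness,
#' inclusion counts, gap channels) is jittered within class-dependent
#' ranges; the whole cohort is a deterministic function of `seed`.
#'
#' @param n_per_class colonies per class.
#' @param seed integer master seed.
#' @param grid,pitch forwarded to [phantom_spec()].
#' @param radius_range range the per-colony footprint radius is drawn
#'   from, um (the default keeps bounding boxes above the 14,250-um^2 QC
#'   threshold).
#' @return list with `tomograms`, `truths`, `labels` and a `manifest`
#'   data frame (id, label, apex height, footprint radius, gap ratio).
#' @export
generate_cohort <- function(n_per_class, seed = 1L,
                            grid = c(24L, 480L, 480L),
                            pitch = ht_default_pitch(),
                            radius_range = c(61, 67)) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  labels <- rep(c("undifferentiated", "differentiating"), each = n_per_class)
  seeds <- sample.int(2^30, 2 * n_per_class)
  radii <- runif(2 * n_per_class, radius_range[1], radius_range[2])
  toms <- vector("list", 2 * n_per_class)
  truths <- vector("list", 2 * n_per_class)
  for (i in seq_along(labels)) {
    sp <- phantom_spec(labels[i], grid = grid, pitch = pitch,
                       footprint_radius = radii[i], seed = seeds[i])
    ph <- generate_phantom(sp)
    toms[[i]] <- ph$tomogram
    truths[[i]] <- ph$truth
  }
  manifest <- data.frame(
    id = vapply(toms, function(t) t$id, character(1)),
    label = labels,
    apex_height = vapply(truths, function(tr) tr$apex_height, numeric(1)),
    footprint_radius = radii,
    gap_area_ratio = vapply(truths, function(tr) tr$gap_area_ratio, numeric(1)),
    stringsAsFactors = FALSE)
  list(tomograms = toms, truths = truths, labels = labels,
       manifest = manifest)
}
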