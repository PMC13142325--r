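#' Patch-grid specification
#'
#' Training patches are stored at 119.3 um so a random 79.6-um crop can be
#' taken at augmentation time; evaluation patches are stored at 79.6 um and
#' cropped centrally (the identity window). The grid stride is 39.8 um and
#' the tiling window is the mask's bounding square padded by a 20-um margin
#' where available. Vertically, patches span 11.4 um above the substrate
#' surface, and the z slices become the network's input channels.
#'
#' @param mode `"train"` or `"eval"`; sets `stored_size`.
#' @param stored_size stored patch side, um.
#' @param crop_size cropped (network input) side, um.
#' @param stride grid spacing, um.
#' @param margin bounding-square margin, um.
#' @param zcrop vertical crop above the substrate, um.
#' @param min_overlap_frac minimum fraction of the patch footprint inside
#'   the colony mask for a grid origin to be kept (0 reproduces strict grid
#'   tiling).
#' @return object of class `patch_spec`.
#' @export
patch_spec <- function(mode = c("eval", "train"), stored_size = NULL,
                       crop_size = 79.6, stride = 39.8, margin = 20,
                       zcrop = 11.4, min_overlap_frac = 0.10) {
  mode <- match.arg(mode)
  if (is.null(stored_size))
    stored_size <- if (mode == "train") 119.3 else 79.6
  stopifnot(crop_size <= stored_size, stride > 0, zcrop > 0)
  structure(list(mode = mode, stored_size = stored_size,
                 crop_size = crop_size, stride = stride, margin = margin,
                 zcrop = zcrop, min_overlap_frac = min_overlap_frac),
            class = "patch_spec")
}

#' Tile a colony mask into patch origins
#'
#' Origins form a `stride`-spaced grid over the mask's bounding square
#' padded by `margin` um in all four directions where the image allows,
#' clipped to image bounds. Origins whose `crop_size` footprint overlaps
#' the mask by less than `min_overlap_frac` are dropped.
#'
#' @param mask2d footprint [map2d] or logical matrix.
#' @param spec a [patch_spec].
#' @param pitch `(dy, dx)` um; taken from `mask2d` when it is a [map2d].
#' @return two-column matrix of (y, x) origins in um (top-left corners of
#'   the crop window); zero rows for an empty mask.
#' @export
tile_patches <- function(mask2d, spec = patch_spec(), pitch = NULL) {
  m <- if (inherits(mask2d, "map2d")) mask2d$values else mask2d
  if (is.null(pitch))
    pitch <- if (inherits(mask2d, "map2d")) mask2d$pitch else
      ht_default_pitch()[2:3]
  empty <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("y_um", "x_um")))
  if (!any(m)) return(empty)
  ij <- which(m, arr.ind = TRUE)
  ylim <- (range(ij[, 1]) - c(1, 0)) * pitch[1]
  xlim <- (range(ij[, 2]) - c(1, 0)) * pitch[2]
  side <- max(diff(ylim), diff(xlim))
  ywin <- mean(ylim) + c(-0.5, 0.5) * side + c(-1, 1) * spec$margin
  xwin <- mean(xlim) + c(-0.5, 0.5) * side + c(-1, 1) * spec$margin
  ywin <- pmin(pmax(ywin, 0), nrow(m) * pitch[1])
  xwin <- pmin(pmax(xwin, 0), ncol(m) * pitch[2])
  origins_axis <- function(win, bound) {
    W <- diff(win)
    if (W < spec$crop_size)
      return(max(0, min(win[1], bound - spec$crop_size)))
    win[1] + spec$stride * (0:floor((W - spec$crop_size) / spec$stride))
  }
  oy <- origins_axis(ywin, nrow(m) * pitch[1])
  ox <- origins_axis(xwin, ncol(m) * pitch[2])
  grid <- cbind(y_um = rep(oy, times = length(ox)),
                x_um = rep(ox, each = length(oy)))
  if (spec$min_overlap_frac > 0) {
    cp <- round(spec$crop_size / pitch[2])
    keep <- vapply(seq_len(nrow(grid)), function(i) {
      r0 <- floor(grid[i, 1] / pitch[1])
      c0 <- floor(grid[i, 2] / pitch[2])
      rr <- (r0 + 1L):min(r0 + cp, nrow(m))
      cc <- (c0 + 1L):min(c0 + cp, ncol(m))
      sum(m[rr, cc]) / cp^2 >= spec$min_overlap_frac
    }, logical(1))
    grid <- grid[keep, , drop = FALSE]
  }
  grid
}

#' Linear RI normalization to the unit interval
#'
#' Maps RI 1.330 to 0 and 1.400 to 1; out-of-range values are clipped.
#'
#' @param values numeric array of RI values.
#' @return array of the same shape in `[0, 1]`.
#' @export
normalize_ri <- function(values)
  pmin(pmax((values - 1.330) / 0.070, 0), 1)

#' Extract one normalized patch
#'
#' The stored block is `spec$stored_size` um wide, centred on the grid cell
#' at `origin`; for `mode = "train_random"` the `crop_size` window is taken
#' at a random position inside the stored block, for `mode = "eval_center"`
#' centrally. The vertical window spans `round(zcrop/dz)` slices starting
#' at the substrate slice and is permuted into the channel dimension.
#' Out-of-bounds voxels are padded with medium RI 1.337. Values are then
#' normalized with [normalize_ri()].
#'
#' @param t a [tomogram].
#' @param origin `(y, x)` um top-left corner of the crop grid cell.
#' @param spec a [patch_spec].
#' @param mode `"eval_center"` or `"train_random"`.
#' @param seed integer seed for the random crop (same seed, same crop).
#' @param label optional class label.
#' @return object of class `ht_patch`: `values` array
#'   `(channels, y, x)` in `[0, 1]`, `origin`, `label`, `colony_id`.
#' @export
extract_patch <- function(t, origin, spec = patch_spec(),
                          mode = c("eval_center", "train_random"),
                          seed = NULL, label = "unlabeled") {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "tomogram"))
  dz <- t$pitch[1]; dy <- t$pitch[2]; dx <- t$pitch[3]
  nz <- dim(t$ri)[1]
  sz <- locate_substrate(t)
  nchan <- round(spec$zcrop / dz)
  if (sz + nchan - 1L > nz)
    stop("vertical crop exceeds the volume height above the substrate")
  crop_px <- round(spec$crop_size / dx)
  stored_px <- round(spec$stored_size / dx)
  off_um <- (spec$stored_size - spec$crop_size) / 2
  sy0 <- floor((origin[1] - off_um) / dy)   # stored block, 0-based px
  sx0 <- floor((origin[2] - off_um) / dx)
  slack <- stored_px - crop_px
  if (mode == "train_random") {
    if (!is.null(seed)) set.seed(seed)
    ry <- sample.int(slack + 1L, 1L) - 1L
    rx <- sample.int(slack + 1L, 1L) - 1L
  } else {
    ry <- rx <- slack %/% 2L
  }
  y0 <- sy0 + ry; x0 <- sx0 + rx                    # crop, 0-based px
  vals <- array(1.337, c(nchan, crop_px, crop_px))
  yr <- (y0 + 1L):(y0 + crop_px); xr <- (x0 + 1L):(x0 + crop_px)
  yin <- which(yr >= 1L & yr <= dim(t$ri)[2])
  xin <- which(xr >= 1L & xr <= dim(t$ri)[3])
  if (length(yin) && length(xin))
    vals[, yin, xin] <- t$ri[sz:(sz + nchan - 1L), yr[yin], xr[xin]]
  structure(list(values = normalize_ri(vals),
                 origin = as.numeric(origin), label = label,
                 colony_id = t$id),
            class = "ht_patch")
}

#' Training-time patch augmentation
#'
#' In order: horizontal flip in x (p = 0.5), flip in y (p = 0.5), x-y
#' transposition (p = 0.5), then additive i.i.d. Gaussian noise with a
#' standard deviation drawn once per patch from U(0.001, 0.1) in normalized
#' units. The label is unchanged; values are clipped back to `[0, 1]`.
#'
#' @param p an `ht_patch`.
#' @param seed integer seed.
#' @param noise add the Gaussian noise component?
#' @param flips apply the flip/transposition components?
#' @return augmented `ht_patch`.
#' @export
augment_patch <- function(p, seed = NULL, noise = TRUE, flips = TRUE) {
  stopifnot(inherits(p, "ht_patch"))
  if (!is.null(seed)) set.seed(seed)
  v <- p$values
  if (flips) {
    if (stats::runif(1) < 0.5) v <- v[, , dim(v)[3]:1, drop = FALSE]
    if (stats::runif(1) < 0.5) v <- v[, dim(v)[2]:1, , drop = FALSE]
    if (stats::runif(1) < 0.5) v <- aperm(v, c(1, 3, 2))
  }
  if (noise) {
    sdn <- stats::runif(1, 0.001, 0.1)
    v <- pmin(pmax(v + stats::rnorm(length(v), 0, sdn), 0), 1)
  }
  p$values <- v
  p
}

#' Average-pool a patch to a lower resolution
#'
#' Reduces the horizontal resolution by an integer factor by block
#' averaging; used for reduced-scale training where full 256-px patches
#' are unnecessarily large.
#'
#' @param p an `ht_patch`.
#' @param factor integer downsampling factor dividing the patch size.
#' @return pooled `ht_patch`.
#' @export
pool_patch <- function(p, factor = 4L) {
  v <- p$values
  d <- dim(v)
  stopifnot(d[2] %% factor == 0L, d[3] %% factor == 0L)
  ny <- d[2] %/% factor; nx <- d[3] %/% factor
  dim(v) <- c(d[1], factor, ny, factor, nx)
  v <- aperm(v, c(2, 4, 1, 3, 5))
  dim(v) <- c(factor * factor, d[1] * ny * nx)
  out <- colMeans(v)
  dim(out) <- c(d[1], ny, nx)
  p$values <- out
  p
}

#' Bundle patches into a dense set
#'
#' @param patches list of `ht_patch` objects of identical shape.
#' @return object of class `ht_patch_set`: `values` `(C, H, W, N)`,
#'   `labels`, `origins`, `colony_ids`.
#' @export
patch_set <- function(patches) {
  stopifnot(length(patches) >= 1L)
  d <- dim(patches[[1]]$values)
  values <- array(0, c(d, length(patches)))
  for (i in seq_along(patches)) values[, , , i] <- patches[[i]]$values
  structure(list(values = values,
                 labels = vapply(patches, function(p) p$label, character(1)),
                 origins = t(vapply(patches, function(p) p$origin,
                                    numeric(2))),
                 colony_ids = vapply(patches, function(p) p$colony_id,
                                     character(1))),
            class = "ht_patch_set")
}

#' Sample labelled patches from one colony
#'
#' Tiles the footprint, then draws `n` patches cycling over the grid
#' origins (random crops in `"train_random"` mode give distinct patches on
#' repeated visits of the same origin).
#'
#' @param t a [tomogram].
#' @param mask2d footprint mask.
#' @param label class label for all patches.
#' @param n number of patches.
#' @param spec a [patch_spec].
#' @param mode crop mode, see [extract_patch()].
#' @param pool optional integer pooling factor (see [pool_patch()]).
#' @param augment apply [augment_patch()]?
#' @param seed integer seed.
#' @return list of `ht_patch`.
#' @export
sample_colony_patches <- function(t, mask2d, label, n,
                                  spec = patch_spec("train"),
                                  mode = "train_random", pool = NULL,
                                  augment = FALSE, seed = 1L) {
  grid <- tile_patches(mask2d, spec,
                       pitch = t$pitch[2:3])
  if (nrow(grid) == 0L) return(list())
  set.seed(seed)
  seeds <- sample.int(2^30, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    o <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    p <- extract_patch(t, o, spec, mode = mode, seed = seeds[i],
                       label = label)
    if (augment) p <- augment_patch(p, seed = seeds[i] + 1L)
    if (!is.null(pool)) p <- pool_patch(p, pool)
    out[[i]] <- p
  }
  out
}
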