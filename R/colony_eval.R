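#' Assemble a spatial P_undiff map from patch predictions
#'
#' Patch probabilities are placed on the stride lattice, and the colony
#' probability is their plain arithmetic mean (the colony score is defined
#' on the patch list, not on rendered pixels). For display, an optional
#' full-resolution rendering averages the overlapping 79.6-um patch
#' footprints per pixel.
#'
#' @param preds data frame or matrix-like with columns `y_um`, `x_um`,
#'   `pundiff` (one row per patch), or a list of `(origin, p)` pairs.
#' @param spec the [patch_spec] used for tiling (for stride/footprint).
#' @param render_shape optional `(ny, nx)` pixel shape; when given, a
#'   per-pixel rendered [map2d] is attached.
#' @param pitch `(dy, dx)` um for rendering.
#' @param threshold colony-call threshold, see [call_colony()].
#' @return object of class `pundiff_map`: `grid` (lattice matrix, NA where
#'   no patch), `origins`, `pundiff`, `colony_pundiff`, `call`, optionally
#'   `rendered`.
#' @export
assemble_pundiff_map <- function(preds, spec = patch_spec(),
                                 render_shape = NULL,
                                 pitch = ht_default_pitch()[2:3],
                                 threshold = 0.5) {
  if (is.list(preds) && !is.data.frame(preds) && !is.matrix(preds))
    preds <- do.call(rbind, lapply(preds, function(e)
      data.frame(y_um = e[[1]][1], x_um = e[[1]][2], pundiff = e[[2]])))
  preds <- as.data.frame(preds)
  if (nrow(preds) == 0L) stop("no patch predictions to assemble")
  stopifnot(all(c("y_um", "x_um", "pundiff") %in% names(preds)),
            all(preds$pundiff >= 0 & preds$pundiff <= 1))
  iy <- round((preds$y_um - min(preds$y_um)) / spec$stride) + 1L
  ix <- round((preds$x_um - min(preds$x_um)) / spec$stride) + 1L
  grid <- matrix(NA_real_, max(iy), max(ix))
  grid[cbind(iy, ix)] <- preds$pundiff
  colony <- mean(preds$pundiff)
  out <- structure(list(grid = grid,
                        origins = as.matrix(preds[, c("y_um", "x_um")]),
                        pundiff = preds$pundiff,
                        colony_pundiff = colony,
                        call = call_from_score(colony, threshold)),
                   class = "pundiff_map")
  if (!is.null(render_shape)) {
    acc <- matrix(0, render_shape[1], render_shape[2])
    cnt <- matrix(0, render_shape[1], render_shape[2])
    cp_y <- round(spec$crop_size / pitch[1])
    cp_x <- round(spec$crop_size / pitch[2])
    for (i in seq_len(nrow(preds))) {
      r0 <- floor(preds$y_um[i] / pitch[1])
      c0 <- floor(preds$x_um[i] / pitch[2])
      rr <- max(r0 + 1L, 1L):min(r0 + cp_y, render_shape[1])
      cc <- max(c0 + 1L, 1L):min(c0 + cp_x, render_shape[2])
      acc[rr, cc] <- acc[rr, cc] + preds$pundiff[i]
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
    ren <- acc / ifelse(cnt > 0, cnt, NA)
    out$rendered <- map2d(ren, pitch = pitch, kind = "pundiff")
  }
  out
}

call_from_score <- function(p, threshold = 0.5)
  if (p > threshold) "undifferentiated" else "differentiating"

#' Colony-level pluripotency call
#'
#' A colony is called undifferentiated iff its mean patch probability
#' strictly exceeds the threshold; a colony at exactly 0.5 is called
#' differentiating.
#'
#' @param m a `pundiff_map` (or a bare numeric colony probability).
#' @param threshold decision threshold (default 0.5).
#' @return `"undifferentiated"` or `"differentiating"`.
#' @export
call_colony <- function(m, threshold = 0.5) {
  p <- if (inherits(m, "pundiff_map")) m$colony_pundiff else as.numeric(m)
  stopifnot(p >= 0, p <= 1)
  call_from_score(p, threshold)
}

#' @export
print.pundiff_map <- function(x, ...) {
  cat(sprintf("<pundiff_map> %d patches, colony P_undiff = %.3f -> %s\n",
              length(x$pundiff), x$colony_pundiff, x$call))
  invisible(x)
}

#' Evaluate one colony end to end
#'
#' Tiles the footprint with the evaluation grid, extracts centred patches,
#' predicts per-patch P_undiff and assembles the colony call.
#'
#' @param m a trained `ht_model`.
#' @param t a [tomogram].
#' @param mask2d footprint mask (computed with [segment_colony_2d()] when
#'   `NULL`).
#' @param spec evaluation [patch_spec].
#' @param pool optional pooling factor matching the model input size.
#' @return a `pundiff_map`.
#' @export
evaluate_colony <- function(m, t, mask2d = NULL, spec = patch_spec("eval"),
                            pool = NULL) {
  if (is.null(mask2d)) mask2d <- segment_colony_2d(t)
  grid <- tile_patches(mask2d, spec, pitch = t$pitch[2:3])
  if (nrow(grid) == 0L) stop("no patches cover the colony footprint")
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    p <- extract_patch(t, grid[i, ], spec, mode = "eval_center")
    if (!is.null(pool)) p <- pool_patch(p, pool)
    p
  })
  ps <- patch_set(patches)
  pu <- predict_patches(m, ps)
  assemble_pundiff_map(data.frame(y_um = grid[, 1], x_um = grid[, 2],
                                  pundiff = pu), spec)
}
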