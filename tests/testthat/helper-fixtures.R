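# Shared fixtures, generated lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# one standard phantom per class (default study conditions, fixed seeds)
fixture_phantom <- function(class = "undifferentiated") {
  key <- paste0("ph_", substr(class, 1, 6))
  if (is.null(.fixtures[[key]])) {
    seed <- if (class == "undifferentiated") 401L else 402L
    .fixtures[[key]] <- generate_phantom(phantom_spec(class, seed = seed))
  }
  .fixtures[[key]]
}

fixture_masks <- function(class = "undifferentiated") {
  key <- paste0("mk_", substr(class, 1, 6))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- colony_masks(fixture_phantom(class)$tomogram)
  .fixtures[[key]]
}

# reduced-scale trained classifier shared between the training and the
# pipeline-closure checks (one training run per test session)
fixture_trained <- function() {
  if (is.null(.fixtures$trained))
    .fixtures$trained <- scaled_training_run(n_train = 10L, n_eval = 4L,
                                             patches_per_colony = 40L,
                                             iterations = 30L, seed = 11L)
  .fixtures$trained
}

# small in-memory tomogram with uniform medium and an optional insert
toy_tomogram <- function(nz = 8L, ny = 16L, nx = 16L, value = 1.337,
                         pitch = c(1, 0.5, 0.5), substrate_z = 1L) {
  tomogram(array(value, c(nz, ny, nx)), pitch = pitch,
           substrate_z = substrate_z, id = "toy")
}

# brute-force binary morphology on small grids (the independent oracle)
brute_dilate <- function(m, k) {
  ko <- (dim(k) - 1L) %/% 2L
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- FALSE
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      ii <- i + a - 1L - ko[1]; jj <- j + b - 1L - ko[2]
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          m[ii, jj]) { acc <- TRUE; break }
    }
    out[i, j] <- acc
  }
  out
}

brute_erode <- function(m, k) {
  ko <- (dim(k) - 1L) %/% 2L
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- TRUE
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      ii <- i + a - 1L - ko[1]; jj <- j + b - 1L - ko[2]
      inside <- ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
        m[ii, jj]
      if (!inside) { acc <- FALSE; break }
    }
    out[i, j] <- acc
  }
  out
}

# a tomogram containing one rasterized ellipsoidal blob of given RI and
# horizontal diameter, in medium background, for the lipid rule checks
blob_tomogram <- function(diam_um, ri_blob, nz = 10L, ny = 48L, nx = 48L,
                          pitch = c(0.5, 0.25, 0.25)) {
  ri <- array(1.345, c(nz, ny, nx))   # weak cytoplasm background
  ctr <- c(nz / 2, ny / 2, nx / 2)
  r <- diam_um / 2
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    d2 <- ((z - ctr[1]) * pitch[1])^2 + ((y - ctr[2]) * pitch[2])^2 +
      ((x - ctr[3]) * pitch[3])^2
    if (d2 <= r^2) ri[z, y, x] <- ri_blob
  }
  tomogram(ri, pitch = pitch, substrate_z = 1L, id = "blob")
}
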