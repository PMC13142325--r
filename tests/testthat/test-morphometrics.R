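test_that("thickness map counts occupied voxels times the axial pitch", {
  m3 <- array(FALSE, c(12, 6, 6))
  m3[1:10, , ] <- TRUE
  m3[, 2, 3] <- FALSE                        # one empty column
  tm <- thickness_map(m3, c(0.9496, 0.3, 0.3))
  expect_equal(tm$values[1, 1], 9.496)
  expect_equal(tm$values[2, 3], 0)
})

test_that("thickness statistics honour the boundary inset", {
  h <- 7.2
  tm <- map2d(matrix(h, 80, 80), pitch = c(0.5, 0.5), kind = "thickness")
  m <- matrix(FALSE, 80, 80)
  m[10:70, 10:70] <- TRUE
  st <- thickness_stats(tm, m, inset = 5)
  expect_equal(st$mean, h)
  expect_equal(st$sd, 0)
  ribbon <- matrix(FALSE, 80, 80)
  ribbon[38:45, 10:70] <- TRUE               # 4-um-wide ribbon, 5-um inset
  expect_error(thickness_stats(tm, ribbon, inset = 5), "too small")
})

test_that("sphere fitting recovers exact, planar and noisy surfaces", {
  # voxel columns sampled exactly on a 100-um sphere cap
  pitch <- c(0.5, 0.5, 0.5)
  ny <- nx <- 120L
  yy <- matrix((1:ny) * 0.5, ny, nx); xx <- t(yy)
  rho2 <- (yy - 30)^2 + (xx - 30)^2
  R <- 100
  h <- sqrt(pmax(R^2 - rho2, 0)) - (R - 12)  # 12-um apex
  m2 <- h > 0.25
  nz <- 30L
  m3 <- array(FALSE, c(nz, ny, nx))
  for (z in 1:nz) m3[z, , ] <- ((z - 0.5) * 0.5) < h & m2
  cv <- fit_sphere_curvature(m3, m2, pitch, inset = 5, substrate_z = 1L)
  expect_equal(cv, 0.0100, tolerance = 0.02)
  # flat slab -> near-zero curvature with the 1e5-um radius cap
  slab <- array(FALSE, c(10, 60, 60)); slab[1:6, , ] <- TRUE
  sm <- matrix(TRUE, 60, 60)
  cv0 <- fit_sphere_curvature(slab, sm, c(1, 0.5, 0.5), inset = 3,
                              substrate_z = 1L)
  expect_lte(abs(cv0), 1e-5)
  # degenerate input
  tiny <- array(FALSE, c(4, 8, 8)); tiny[1, 4, 4] <- TRUE
  tm2 <- matrix(FALSE, 8, 8); tm2[4, 4] <- TRUE
  expect_error(fit_sphere_curvature(tiny, tm2, c(1, 1, 1), inset = 0),
               "surface points")
})

test_that("sphere fit tolerates axial noise at the voxel scale", {
  set.seed(21)
  R <- 200; apex <- 9
  ny <- nx <- 160L
  yy <- matrix((1:ny) * 0.5, ny, nx); xx <- t(yy)
  rho2 <- (yy - 40)^2 + (xx - 40)^2
  h <- sqrt(pmax(R^2 - rho2, 0)) - (R - apex)
  h <- h + stats::rnorm(length(h), 0, 0.9496)   # sigma = dz
  m2 <- matrix(rho2 <= 55^2, ny, nx)            # cap footprint
  nz <- 14L
  m3 <- array(FALSE, c(nz, ny, nx))
  for (z in 1:nz) m3[z, , ] <- ((z - 0.5) * 0.9496) < h & m2
  cv <- fit_sphere_curvature(m3, m2, c(0.9496, 0.5, 0.5), inset = 5,
                             substrate_z = 1L)
  expect_equal(cv, 1 / R, tolerance = 0.05)
})

test_that("lipid detection applies the size rule with the peak-RI rescue", {
  m3_of <- function(t) array(TRUE, dim(t$ri))
  small <- blob_tomogram(2, 1.395)             # 2 um, RI 1.395 -> kept
  d <- detect_lipid(small, m3_of(small))
  expect_gt(d$lipid_volume, 0)
  wide_dim <- blob_tomogram(4, 1.385)          # 4 um, peak < 1.40 -> dropped
  d2 <- detect_lipid(wide_dim, m3_of(wide_dim))
  expect_equal(d2$lipid_volume, 0)
  wide_hot <- blob_tomogram(4, 1.405)          # 4 um but peak >= 1.40 -> kept
  d3 <- detect_lipid(wide_hot, m3_of(wide_hot))
  expect_gt(d3$lipid_volume, 0)
  # volume equals voxel count times voxel volume
  expect_equal(d3$lipid_volume,
               length(d3$voxels) * prod(wide_hot$pitch))
})

test_that("lipid recovery matches phantom ground truth", {
  for (cl in c("undifferentiated", "differentiating")) {
    ph <- fixture_phantom(cl)
    mk <- fixture_masks(cl)
    d <- detect_lipid(ph$tomogram, mk$mask3d)
    expect_equal(d$lipid_volume, ph$truth$lipid_volume,
                 tolerance = 0.15)
  }
})

test_that("gap detection drops boundary-proximal components", {
  nz <- 8L; ny <- nx <- 200L; pitch <- c(1, 0.5, 0.5)
  ri <- array(1.337, c(nz, ny, nx))
  yy <- matrix(seq_len(ny), ny, nx); xx <- t(yy)
  disk <- (yy - 100)^2 + (xx - 100)^2 <= 80^2      # 40-um colony
  for (z in 2:7) { sl <- ri[z, , ]; sl[disk] <- 1.36; ri[z, , ] <- sl }
  # interior pocket, > 5 um from the boundary
  pocket <- (yy - 100)^2 + (xx - 100)^2 <= 10^2
  # edge notch hugging the boundary
  notch <- abs(yy - 100) <= 4 & xx >= 168 & xx <= 180 & disk
  for (z in 2:7) {
    sl <- ri[z, , ]; sl[pocket | notch] <- 1.337; ri[z, , ] <- sl
  }
  t <- tomogram(ri, pitch = pitch, substrate_z = 2L)
  g <- detect_gaps(t, disk)
  expect_true(all(g$gap_mask[pocket]))
  expect_false(any(g$gap_mask[notch]))
  expect_equal(g$gap_area_ratio, sum(pocket) / sum(disk), tolerance = 0.02)
  # gap-free colony -> ratio 0
  ph <- fixture_phantom("undifferentiated")
  g0 <- detect_gaps(ph$tomogram, fixture_masks("undifferentiated")$mask2d)
  expect_equal(g0$gap_area_ratio, 0, tolerance = 1e-3)
})

test_that("gap recovery matches phantom ground truth within 10 %", {
  ph <- fixture_phantom("differentiating")
  mk <- fixture_masks("differentiating")
  g <- detect_gaps(ph$tomogram, mk$mask2d)
  expect_gt(ph$truth$gap_area_ratio, 0)
  expect_equal(g$gap_area_ratio, ph$truth$gap_area_ratio, tolerance = 0.10)
})

test_that("shape descriptors: disk, 2:1 ellipse and a concave star", {
  px <- 0.5
  yy <- matrix(seq_len(240), 240, 240); xx <- t(yy)
  disk <- (yy - 120)^2 + (xx - 120)^2 <= 90^2
  sd1 <- shape_descriptors(disk, c(px, px))
  expect_equal(sd1$roundness, 1.0, tolerance = 0.03)
  expect_gte(sd1$solidity, 0.98)
  expect_lte(sd1$eccentricity, 0.1)
  expect_equal(sd1$area, sum(disk) * px^2)
  ell <- ((yy - 120) / 100)^2 + ((xx - 120) / 50)^2 <= 1
  sd2 <- shape_descriptors(ell, c(px, px))
  expect_equal(sd2$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  star <- disk & !(abs(yy - 120) < 12 & xx > 120)   # slot cut from the disk
  sd3 <- shape_descriptors(star, c(px, px))
  expect_lt(sd3$solidity, 1)
  expect_lt(sd3$solidity, sd1$solidity)
  expect_error(shape_descriptors(matrix(FALSE, 8, 8), c(1, 1)), "small")
})

test_that("boundary contrast matches the sharp-disk value and vanishes when uniform", {
  nz <- 6L; ny <- nx <- 200L; pitch <- c(1, 0.5, 0.5)
  ri <- array(1.337, c(nz, ny, nx))
  yy <- matrix(seq_len(ny), ny, nx); xx <- t(yy)
  disk <- (yy - 100)^2 + (xx - 100)^2 <= 60^2
  for (z in 2:5) { sl <- ri[z, , ]; sl[disk] <- 1.36; ri[z, , ] <- sl }
  t <- tomogram(ri, pitch = pitch, substrate_z = 2L)
  expect_equal(boundary_ri_contrast(t, disk), 1.36 - 1.337,
               tolerance = 0.01)
  # uniform field: zero contrast across any boundary
  u <- toy_tomogram(ny = 100, nx = 100, value = 1.35)
  um <- matrix(FALSE, 100, 100); um[30:70, 30:70] <- TRUE
  expect_equal(boundary_ri_contrast(u, um), 0)
  # blurring the edge reduces the contrast
  ri_b <- ri
  for (z in 2:5) ri_b[z, , ] <- as.matrix(EBImage::gblur(ri[z, , ], 6))
  tb <- tomogram(ri_b, pitch = pitch, substrate_z = 2L)
  expect_lt(boundary_ri_contrast(tb, disk), boundary_ri_contrast(t, disk))
})

test_that("dry mass follows the refractive-increment conversion", {
  t <- toy_tomogram(nz = 4, ny = 6, nx = 6,
                    pitch = c(0.9496, 0.3109, 0.3109), substrate_z = 1L)
  t$ri[2, 3, 3] <- 1.374
  m3 <- array(TRUE, dim(t$ri))
  dm <- dry_mass(t, m3)
  hand <- (1.374 - 1.337) / 0.185 * (0.9496 * 0.3109 * 0.3109)
  expect_equal(dm$total, hand, tolerance = 1e-10)
  expect_equal(sum(dm$z_profile), dm$total)
  # medium-only volume has zero mass; doubling alpha halves every mass
  t0 <- toy_tomogram()
  expect_equal(dry_mass(t0, array(TRUE, dim(t0$ri)))$total, 0)
  dm2 <- dry_mass(t, m3, alpha = 0.37)
  expect_equal(dm2$total, dm$total / 2)
  expect_error(dry_mass(t, m3, alpha = 0), "positive")
  # z-window helper integrates slices whose centres fall in the window
  dmw <- dry_mass(t, m3, z_windows = list(low = c(0.9496, 2 * 0.9496)))
  expect_equal(unname(dmw$window_mass["low"]), dm$z_profile[2])
})

test_that("spatial moments: symmetry, degeneracy and the summation oracle", {
  px <- c(0.5, 0.5)
  yy <- matrix(seq_len(64), 64, 64); xx <- t(yy)
  disk <- (yy - 32)^2 + (xx - 32)^2 <= 25^2
  uni <- spatial_moments(matrix(1, 64, 64), disk, px)
  expect_equal(unname(uni["centroid_disp"]), 0, tolerance = 1e-9)
  pt <- matrix(0, 64, 64)
  ij <- which(disk, arr.ind = TRUE)
  ctr <- round(colMeans(ij))
  pt[ctr[1], ctr[2]] <- 5
  ptm <- spatial_moments(pt, disk, px)
  expect_lt(unname(ptm["spread"]), 0.03)
  zero <- spatial_moments(matrix(0, 64, 64), disk, px)
  expect_true(all(zero == 0))
  expect_true(isTRUE(attr(zero, "degenerate")))
  set.seed(31)
  for (trial in 1:5) {
    v <- matrix(stats::runif(32 * 32), 32, 32)
    msk <- matrix(stats::runif(32 * 32) < 0.6, 32, 32)
    if (!any(msk)) next
    got <- spatial_moments(v, msk, px)
    w <- v[msk]; ijm <- which(msk, arr.ind = TRUE)
    py <- ijm[, 1] * px[1]; pxx <- ijm[, 2] * px[2]
    tot <- sum(w)
    cy <- sum(w * py) / tot; cx <- sum(w * pxx) / tot
    r <- sqrt((py - cy)^2 + (pxx - cx)^2)
    req <- sqrt(sum(msk) * px[1] * px[2] / pi)
    mr <- sum(w * r) / tot
    m2 <- sum(w * (r - mr)^2) / tot
    expect_equal(unname(got["spread"]), sqrt(sum(w * r^2) / tot) / req)
    expect_equal(unname(got["skewness"]), sum(w * (r - mr)^3) / tot / m2^1.5)
    expect_equal(unname(got["kurtosis"]), sum(w * (r - mr)^4) / tot / m2^2)
    expect_equal(unname(got["centroid_disp"]),
                 sqrt((cy - mean(py))^2 + (cx - mean(pxx))^2) / req)
  }
})

test_that("surface profiles are normalized and shaped by the geometry", {
  slab <- array(FALSE, c(10, 60, 100)); slab[1:6, 10:50, 10:90] <- TRUE
  sm <- matrix(FALSE, 60, 100); sm[10:50, 10:90] <- TRUE
  pr <- surface_profile(slab, sm, c(1, 0.5, 0.5), n_points = 50)
  expect_equal(range(pr$position), c(0, 1))
  inner <- pr$height[pr$position > 0.1 & pr$position < 0.9]
  expect_true(all(abs(inner - 6) < 1e-9))
  # spherical-cap phantom: symmetric with the apex near the middle
  ph <- fixture_phantom("undifferentiated")
  mk <- fixture_masks("undifferentiated")
  prc <- surface_profile(mk$mask3d, mk$mask2d, ph$tomogram$pitch,
                         substrate_z = mk$substrate_z)
  expect_equal(range(prc$position), c(0, 1))
  expect_true(abs(prc$position[which.max(prc$height)] - 0.5) < 0.2)
  expect_equal(max(prc$height), ph$truth$apex_height,
               tolerance = 0.15)
  expect_error(surface_profile(slab, matrix(FALSE, 60, 100), c(1, 0.5, 0.5)),
               "degenerate")
})

test_that("the QC rule is strict below 14,250 um^2", {
  px <- c(1, 1)
  m_small <- matrix(FALSE, 200, 200); m_small[1:100, 1:140] <- TRUE  # 14,000
  expect_false(qc_colony(m_small, px))
  m_exact <- matrix(FALSE, 200, 200); m_exact[1:114, 1:125] <- TRUE  # 14,250
  expect_true(qc_colony(m_exact, px))
  m_big <- matrix(FALSE, 200, 200); m_big[1:120, 1:120] <- TRUE      # 14,400
  expect_true(qc_colony(m_big, px))
})

test_that("the property vector has the full 31-entry schema and is deterministic", {
  ph <- fixture_phantom("undifferentiated")
  mk <- fixture_masks("undifferentiated")
  pv <- compute_property_vector(ph$tomogram, mk)
  expect_length(pv, 31L)
  expect_identical(names(unclass(pv)), property_names())
  expect_true(all(is.finite(pv)))
  expect_gt(pv["roundness"], 0); expect_lte(pv["roundness"], 1)
  expect_gt(pv["solidity"], 0); expect_lte(pv["solidity"], 1)
  expect_gte(pv["eccentricity"], 0); expect_lt(pv["eccentricity"], 1)
  expect_gte(pv["gap_area_ratio"], 0); expect_lte(pv["gap_area_ratio"], 1)
  pv2 <- compute_property_vector(ph$tomogram, mk)
  expect_identical(unclass(pv), unclass(pv2))
  # volume conservation: 3D mask volume equals integrated thickness
  tm <- thickness_map(mk$mask3d, ph$tomogram$pitch)
  expect_equal(unname(pv["volume"]),
               sum(tm$values) * prod(ph$tomogram$pitch[2:3]))
})

test_that("a flat colony scores lower aspect ratio, thickness and curvature", {
  und <- compute_property_vector(fixture_phantom("undifferentiated")$tomogram,
                                 fixture_masks("undifferentiated"))
  dif <- compute_property_vector(fixture_phantom("differentiating")$tomogram,
                                 fixture_masks("differentiating"))
  expect_gt(und["aspect_ratio"], dif["aspect_ratio"])
  expect_gt(und["mean_thickness"], dif["mean_thickness"])
  expect_gt(und["curvature"], dif["curvature"])
  expect_gt(dif["gap_area_ratio"], und["gap_area_ratio"])
})

test_that("properties are invariant under a 90-degree rotation of the volume", {
  ph <- fixture_phantom("differentiating")
  t <- ph$tomogram
  pv <- compute_property_vector(t, colony_masks(t))
  rot <- t
  rot$ri <- aperm(t$ri, c(1, 3, 2))[, , dim(t$ri)[2]:1]   # 90-deg in-plane
  pv_r <- compute_property_vector(rot, colony_masks(rot))
  for (nm in property_names())
    expect_equal(unname(pv_r[nm]), unname(pv[nm]), tolerance = 1e-6,
                 label = nm)
})
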