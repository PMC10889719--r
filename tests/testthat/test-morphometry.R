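test_that("a half-filled slab gives BV/TV = 50% and BV/TV + Po = 100%", {
  m <- compute_morphometry(phantom_slab(48, 0.5))
  expect_equal(m$`BV/TV`, 50)
  expect_equal(m$`BV/TV` + m$Po, 100)
  expect_equal(m$TV, 48^3)
  expect_equal(m$BV, 48^3 / 2)
})

test_that("a voxelized ball matches the analytic sphere formulas and topology", {
  m <- compute_morphometry(phantom_ball(51, 20))
  expect_equal(m$EuN, 1L)
  expect_equal(m$`Obj.N`, 1L)
  expect_equal(m$`Po.N(cl)`, 0L)
  expect_lt(abs(m$BV - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.02)
  expect_lt(abs(m$BS - 4 * pi * 20^2) / (4 * pi * 20^2), 0.05)
  # centred ball: centroid at the grid centre
  expect_equal(unname(c(m$Ct.X, m$Ct.Y, m$Ct.Z)), rep(26, 3), tolerance = 0.1)
})

test_that("a hollow shell has one object, one closed pore and Euler number 2", {
  m <- compute_morphometry(phantom_hollow_shell(51, 20, 10))
  expect_equal(m$EuN, 2L)
  expect_equal(m$`Obj.N`, 1L)
  expect_equal(m$`Po.N(cl)`, 1L)
})

test_that("parallel plates recover thickness, separation and strong anisotropy", {
  m <- compute_morphometry(phantom_plates(60, 5, 10, spacing_um = 11))
  expect_lte(abs(m$`Tb.Th` - 5 * 11) / (5 * 11), 0.10)
  # even-width gaps read one voxel low (no voxel sits at the continuous gap
  # centre), which lands exactly on the 10% bound at a 10-voxel gap
  expect_lte(abs(m$`Tb.Sp` - 10 * 11) / (10 * 11), 0.10)
  expect_gt(m$DA, 3)
})

test_that("surface error decreases under mesh refinement", {
  s_true <- 4 * pi * 20^2
  m1 <- compute_morphometry(phantom_ball(51, 20))
  # 2x supersampled ball: radius 40 in a 102-voxel grid at half spacing
  m2 <- compute_morphometry(phantom_ball(101, 40, spacing_um = 0.5))
  err1 <- abs(m1$BS - s_true) / s_true
  err2 <- abs(m2$BS - s_true) / s_true  # BS already in um^2 via the 0.5 um spacing
  expect_lt(err2, err1)
})

test_that("slab thickness is invariant to in-plane extent", {
  th <- vapply(c(32, 48, 64), function(n) {
    v <- array(FALSE, c(n, n, 32)); v[, , 9:16] <- TRUE
    compute_morphometry(binary_volume(v, 1))$`Tb.Th`
  }, numeric(1))
  expect_lt(max(th) - min(th), 1e-9)
  # an 8-voxel slab reads 2*4 - 1 = 7: the voxel-centre transform cannot see
  # the inscribed ball centred between two voxel planes
  expect_equal(unname(th[1]), 7, tolerance = 0.01)
})

test_that("an isotropic random field has near-unit anisotropy", {
  m <- compute_morphometry(binary_volume(fx_phantom()$mineral_mask, 11))
  expect_gte(m$DA, 1)
  expect_lte(m$DA, 1.3)
})

test_that("separation equals the thickness of the complement (shared code path)", {
  v <- fx_phantom()$mineral_mask[1:32, 1:32, 1:32]
  m_fg <- compute_morphometry(binary_volume(v, 1))
  m_bg <- compute_morphometry(binary_volume(!v, 1))
  expect_equal(m_fg$`Tb.Sp`, m_bg$`Tb.Th`)
  expect_equal(m_fg$`Tb.Th`, m_bg$`Tb.Sp`)
})

test_that("degenerate prisms yield defined values, not errors", {
  full <- compute_morphometry(binary_volume(array(TRUE, c(16, 16, 16)), 1))
  expect_equal(full$`BV/TV`, 100)
  expect_equal(full$BS, 0)
  expect_true(is.na(full$`Tb.Th`))
  empty <- suppressWarnings(
    compute_morphometry(binary_volume(array(FALSE, c(16, 16, 16)), 1)))
  expect_equal(empty$`BV/TV`, 0)
  expect_equal(empty$Po, 100)
})

test_that("binarization rules select the stated voxels", {
  lv <- fx_phantom()$labeled
  both <- binarize_volume(lv, "labels:bone,graft")
  expect_identical(both$voxels, array(lv$voxels %in% 1:2, dim(lv$voxels)))
  bone <- binarize_volume(lv, "labels:bone")
  expect_identical(bone$voxels, array(lv$voxels == 1L, dim(lv$voxels)))
  ct0 <- simulate_microct(lv, 0, 0)
  expect_identical(binarize_volume(ct0, "otsu", 11)$voxels,
                   fx_phantom()$mineral_mask)
  x <- array(runif(27), c(3, 3, 3))
  expect_identical(binarize_volume(x, "fixed:0.5", 1)$voxels,
                   array(x > 0.5, dim(x)))
})

test_that("prism tiling matches the exact-division and floor rules", {
  # ROI of exactly 1024 x 1024 x 460 um at 1 um voxels -> 2 x 2 x 2 prisms
  v <- array(TRUE, c(64, 64, 58))
  g8 <- tile_volume_prisms(binary_volume(v, spacing_um = c(16, 16, 8)),
                           prism_size_um = c(512, 512, 230))
  expect_equal(g8$count, 8L)
  # 1000 um along x -> only one full 512-um prism fits there
  roi <- array(TRUE, c(64, 64, 58)); roi[, 64, ] <- FALSE  # 63 * 16 = 1008 um
  g4 <- tile_volume_prisms(binary_volume(v, spacing_um = c(16, 16, 8)),
                           roi_mask = roi, prism_size_um = c(512, 512, 230))
  expect_equal(g4$count, 4L)
})

test_that("prism retention agrees with a brute-force enumeration inside a cylinder", {
  d <- c(48, 48, 40)
  centre <- (d[1:2] + 1) / 2
  roi <- array(FALSE, d)
  for (k in seq_len(d[3]))
    roi[, , k] <- outer(seq_len(d[1]), seq_len(d[2]), function(i, j)
      (i - centre[1])^2 + (j - centre[2])^2 <= 20^2)
  bv <- binary_volume(array(TRUE, d), 11)
  g <- tile_volume_prisms(bv, roi_mask = roi, prism_size_um = c(132, 132, 110))
  sz <- g$size_vox
  idx <- which(roi, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  starts <- lapply(1:3, function(a) seq(lo[a], d[a] - sz[a] + 1, by = sz[a]))
  brute <- 0
  for (y0 in starts[[1]]) for (x0 in starts[[2]]) for (z0 in starts[[3]]) {
    if (all(roi[y0:(y0 + sz[1] - 1), x0:(x0 + sz[2] - 1), z0:(z0 + sz[3] - 1)]))
      brute <- brute + 1
  }
  expect_equal(g$count, brute)
})

test_that("anisotropic volumes are resampled to the coarsest spacing first", {
  v <- array(FALSE, c(20, 20, 40)); v[, , 11:30] <- TRUE
  m <- compute_morphometry(binary_volume(v, spacing_um = c(2, 2, 1)))
  # after resampling to 2 um the slab is 10 voxels thick; the even-width
  # voxel-centre convention reads 2*5 - 1 = 9 voxels = 18 um
  expect_equal(m$`Tb.Th`, 18, tolerance = 1)
})
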