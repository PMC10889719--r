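test_that("generated mineral fraction hits the target BV/TV within 0.5 pp", {
  ph <- fx_phantom()
  expect_gte(mean(ph$mineral_mask), 0.295)
  expect_lte(mean(ph$mineral_mask), 0.305)
  # graft blobs take the requested share of the mineralized phase
  graft_share <- sum(ph$labeled$voxels == 2L) / sum(ph$mineral_mask)
  expect_lt(abs(graft_share - 0.25), 0.01)
})

test_that("the same spec and seed reproduce the phantom exactly", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_um = 11,
                       correlation_length_um = 33, seed = 123)
  a <- generate_trabecular_volume(spec)
  b <- generate_trabecular_volume(spec)
  expect_identical(a$labeled$voxels, b$labeled$voxels)
  expect_identical(a$grayscale, b$grayscale)
})

test_that("near-saturating BV/TV produces one near-solid object", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_um = 11,
                       correlation_length_um = 33, target_bvtv = 0.999,
                       graft_fraction = 0, seed = 1)
  ph <- generate_trabecular_volume(spec)
  expect_gte(mean(ph$mineral_mask), 0.99)
  m <- compute_morphometry(binary_volume(ph$mineral_mask, 11))
  expect_equal(m$`Obj.N`, 1L)
})

test_that("degenerate specs are rejected with a sizing message", {
  expect_error(phantom_spec(grid_shape = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(grid_shape = c(32, 32, 32), voxel_size_um = 1,
                            correlation_length_um = 100), "too small")
  expect_error(phantom_spec(target_bvtv = 1.2), "strictly in")
})

test_that("uncorrupted microCT is two-level with high support equal to the mineral mask", {
  ph <- fx_phantom()
  ct <- simulate_microct(ph$labeled, blur_sigma_vox = 0, noise_sd = 0)
  expect_setequal(unique(as.vector(ct)), c(0.15, 0.85))
  expect_identical(array(ct == 0.85, dim(ct)), ph$mineral_mask)
  expect_error(simulate_microct(ph$labeled, blur_sigma_vox = -1), "non-negative")
})

test_that("Otsu re-binarization recovers the mineral mask at the SNR floor", {
  ph <- fx_phantom()
  bin <- binarize_volume(fx_ct(), "otsu", spacing_um = 11)
  expect_gte(mean(bin$voxels == ph$mineral_mask), 0.98)
})

test_that("Gaussian blur conserves the volume mean", {
  ph <- fx_phantom()
  blurred <- simulate_microct(ph$labeled, blur_sigma_vox = 1.2, noise_sd = 0)
  sharp <- simulate_microct(ph$labeled, blur_sigma_vox = 0, noise_sd = 0)
  expect_lt(abs(mean(blurred) - mean(sharp)), 1e-6)
})

test_that("zero jitter yields identity ground-truth transforms and monotone z", {
  st <- fx_stack_clean()
  expect_true(all(st$truth$tx == 0 & st$truth$ty == 0 &
                    st$truth$theta == 0 & st$truth$s == 1))
  z <- st$truth$z_index[!st$truth$dropped]
  expect_true(all(diff(z) > 0))
})

test_that("jitter draws respect the configured bounds", {
  st <- fx_stack_jitter()
  expect_true(all(abs(st$truth$theta) <= 10))
  expect_true(all(abs(st$truth$tx) <= 20 & abs(st$truth$ty) <= 20))
  expect_true(all(abs(st$truth$s - 1) <= 0.03))
})

test_that("the stored inverse transform undoes the jitter on the class mask", {
  st <- fx_stack_jitter()
  agree <- vapply(c(5L, 20L, 40L), function(i) {
    key <- names(st$masks)[i]
    tr <- st$truth[st$truth$slide_id == as.integer(key), ]
    a <- affine2d(tr$tx, tr$ty, tr$theta, tr$s)
    nr <- nrow(st$masks[[i]])
    back <- warp_image(matrix(as.numeric(st$masks[[i]]), nr), invert_affine(a),
                       interp = "nearest", background = -1)
    # nearest-neighbour resampling legitimately flips pixels on class edges,
    # and empty-margin pixels whose jittered position left the canvas are
    # unrecoverable (tissue itself never leaves: the margin is sized for it);
    # compare recoverable, off-edge pixels
    clean <- st$clean_masks[[i]]
    uniform <- matrix(TRUE, nr, nr)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      uniform <- uniform & (trabekit:::shift_mat(clean, di, dj, -1) == clean)
    }
    ok <- uniform & back >= 0
    mean(back[ok] == clean[ok])
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})

test_that("total dropout is rejected", {
  ph <- fx_phantom()
  sim <- histology_sim_spec(slice_thickness_um = 11, dropout_prob = 0.999,
                            seed = 1)
  expect_error(simulate_histology_stack(ph$labeled, sim), "dropout")
})

test_that("stack simulation is deterministic under a fixed seed", {
  ph <- fx_phantom()
  sim <- histology_sim_spec(slice_thickness_um = 11, max_rotation_deg = 5,
                            max_translation_px = 5, dropout_prob = 0.1,
                            stain_noise_sd = 0.02, seed = 99)
  a <- simulate_histology_stack(ph$labeled, sim)
  b <- simulate_histology_stack(ph$labeled, sim)
  expect_identical(a$truth, b$truth)
  expect_identical(a$slides, b$slides)
})
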