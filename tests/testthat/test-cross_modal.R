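test_that("axis-aligned slicing at native spacing returns the raw planes", {
  ct <- fx_ct()
  cs <- slice_volume(ct, 11)
  expect_equal(length(cs$slices), 64)
  expect_identical(cs$slices[[30]], ct[, , 30])
  restacked <- array(0, dim(ct))
  for (k in seq_along(cs$slices)) restacked[, , k] <- cs$slices[[k]]
  expect_identical(restacked, ct)
})

test_that("an oblique cut of a solid ball produces discs following the chord formula", {
  n <- 64; r <- 20
  co <- (1:n) - (n + 1) / 2
  vol <- array(as.numeric(outer(outer(co^2, co^2, "+"), co^2, "+") <= r^2),
               c(n, n, n))
  cs <- slice_volume(vol, 1, normal = c(0, sin(pi / 6), cos(pi / 6)))
  # the ball centre sits mid-range of the symmetric slice offsets
  pos_center <- (min(cs$positions_um) + max(cs$positions_um)) / 2
  for (i in seq_along(cs$slices)) {
    dist <- abs(cs$positions_um[i] - pos_center)
    r_exp <- sqrt(max(0, r^2 - dist^2))
    if (r_exp < 8) next  # near the pole the radius changes faster than a voxel
    r_obs <- sqrt(sum(cs$slices[[i]] > 0.5) / pi)
    expect_lt(abs(r_obs - r_exp), 1)
  }
})

test_that("a plane that misses the volume is rejected", {
  vol <- array(0, c(32, 32, 32))
  vol[10:20, 10:20, 10:20] <- 1
  expect_error(slice_volume(vol, 1, normal = c(0, 0, 1),
                            slice_spacing_um = 1e6), "outside")
})

test_that("bell-curve fitting recovers the peak of noise-free Gaussian counts", {
  z <- 1:80
  counts <- 50 * exp(-(z - 42)^2 / (2 * 2.5^2)) + 3
  pk <- fit_peak(counts)
  expect_false(pk$fallback)
  expect_lt(abs(pk$fit[["mu"]] - 42), 1e-3)
  expect_equal(pk$matched_index, 42L)
  expect_lt(abs(pk$fit[["b"]] - 3), 0.1)
})

test_that("a symmetric two-point tie resolves to the centre by symmetry", {
  z <- 1:80
  counts <- 50 * exp(-(z - 42.5)^2 / (2 * 4)) + 2
  pk <- fit_peak(counts)
  expect_lt(abs(pk$fit[["mu"]] - 42.5), 0.01)
})

test_that("flat counts fall back to the argmax with a flag", {
  pk <- fit_peak(rep(5, 20))
  expect_true(pk$fallback)
  expect_equal(pk$matched_index, 1L)
  expect_error(fit_peak(rep(0, 20)), "zero")
  expect_error(fit_peak(c(1, 2)), "at least 5")
})

test_that("a CT slice used as the query peaks at its own index", {
  ct_stack <- slice_volume(fx_ct(), 11)
  m <- matcher(max_keypoints = 120, on_gradient = TRUE)
  prof <- keypoint_profile(ct_stack$slices[[30]], ct_stack, m)
  expect_equal(which.max(prof$counts), 30L)
  expect_lte(abs(prof$matched_index - 30), 1)
})

test_that("a jitter-free histology slide matches its source z index with a clear peak", {
  st <- fx_stack_clean()
  ct_stack <- slice_volume(fx_ct(), 11)
  m <- matcher(max_keypoints = 150, on_gradient = TRUE)
  key <- "40"
  prof <- keypoint_profile(st$slides[[key]], ct_stack, m)
  expect_equal(which.max(prof$counts),
               st$truth$z_index[st$truth$slide_id == 40L])
  expect_gte(prof$peak_to_background, 5)
})

test_that("zero-jitter assembly reproduces the ground-truth class volume", {
  st <- fx_stack_clean()
  ct_stack <- slice_volume(fx_ct(), 11)
  keys <- names(st$slides)[10:19]
  sub <- register_and_assemble(st$slides[keys], st$masks[keys],
                               ct_stack, matcher(max_keypoints = 300,
                                                 on_gradient = TRUE))
  truth_z <- st$truth$z_index[match(as.integer(keys), st$truth$slide_id)]
  expect_true(all(abs(sub$assignments$matched_index - truth_z) <= 1))
  exact <- sub$assignments$matched_index == truth_z
  expect_gte(mean(exact), 0.9)
  gt <- fx_phantom()$labeled$voxels
  agree <- vapply(which(exact), function(i) {
    k <- sub$assignments$matched_index[i]
    mean(sub$volume$voxels[, , k] == gt[, , k])
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("dropped slides appear exactly as missing planes", {
  ph <- fx_phantom()
  sim <- histology_sim_spec(slice_thickness_um = 11, dropout_prob = 0.15,
                            seed = 6)
  st <- simulate_histology_stack(ph$labeled, sim)
  dropped_z <- st$truth$z_index[st$truth$dropped]
  kept_z <- st$truth$z_index[!st$truth$dropped]
  ct_stack <- slice_volume(fx_ct(), 11)
  # inject unambiguous single-spike profiles so this exercises the missing-
  # plane bookkeeping, not slice-matching accuracy (covered elsewhere)
  spike <- function(z) {
    counts <- rep(1, length(ct_stack$slices)); counts[z] <- 50
    pk <- fit_peak(counts)
    structure(list(counts = counts, fit = pk$fit, matched_index = z,
                   fallback = pk$fallback, peak_to_background = 50),
              class = "match_profile")
  }
  rec <- register_and_assemble(st$slides, st$masks, ct_stack,
                               matcher(max_keypoints = 150, on_gradient = TRUE),
                               refine = FALSE,
                               profiles = lapply(kept_z, spike))
  expect_true(all(dropped_z %in% rec$volume$missing_planes))
  expect_false(any(kept_z %in% rec$volume$missing_planes))
  expect_equal(sort(c(dropped_z, kept_z)), 1:64)
})
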