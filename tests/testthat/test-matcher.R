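test_that("an image matched to itself gives many zero-displacement matches", {
  img <- fx_ct()[, , 30]
  mr <- match_keypoints(img, img, matcher(max_keypoints = 150))
  expect_gt(mr$n_matches, 20)
  expect_equal(mr$keypoints_a, mr$keypoints_b)
  expect_equal(mr$parallel_fraction, 1)
})

test_that("a pure translation is recovered as the median match displacement", {
  set.seed(21)
  img <- trabekit:::cpp_gauss_blur2d(matrix(rnorm(128 * 128), 128, 128), 1.5)
  shifted <- warp_image(img, affine2d(tx = 30, ty = 0))
  mr <- match_keypoints(img, shifted, matcher(max_keypoints = 150))
  disp <- mr$keypoints_b - mr$keypoints_a
  expect_gt(mr$n_matches, 10)
  expect_lt(abs(median(disp[, 1]) - 30), 1)
  expect_lt(abs(median(disp[, 2]) - 0), 1)
  expect_gt(mr$parallel_fraction, 0.8)
})

test_that("matching against noise yields an order of magnitude fewer matches", {
  img <- fx_ct()[, , 30]
  self_n <- match_keypoints(img, img, matcher(max_keypoints = 150))$n_matches
  set.seed(5)
  noise <- matrix(runif(64 * 64), 64, 64)
  noise_n <- match_keypoints(img, noise, matcher(max_keypoints = 150))$n_matches
  expect_lte(noise_n, self_n / 10)
})

test_that("the transformer backend without weights names the fallback", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_error(detect_features(img, matcher(backend = "loftr")), "classical")
})

test_that("the similarity estimate recovers a known transform from matches", {
  set.seed(8)
  a <- affine2d(tx = 6, ty = -4, theta = 12, s = 1.05)
  pts <- cbind(runif(50, 10, 110), runif(50, 10, 110))
  center <- c(60, 60)
  mapped <- apply_affine(a, pts, center = center) + matrix(rnorm(100, 0, 0.2), ncol = 2)
  est <- trabekit:::estimate_similarity(pts, mapped, center)
  expect_lt(abs(est$tx - a$tx), 0.5)
  expect_lt(abs(est$ty - a$ty), 0.5)
  expect_lt(abs(est$theta - a$theta), 0.5)
  expect_lt(abs(est$s - a$s), 0.01)
})
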