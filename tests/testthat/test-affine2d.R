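test_that("composition acts like sequential application on random points", {
  set.seed(42)
  for (rep in 1:20) {
    a <- affine2d(runif(1, -20, 20), runif(1, -20, 20), runif(1, -45, 45),
                  runif(1, 0.8, 1.2))
    b <- affine2d(runif(1, -20, 20), runif(1, -20, 20), runif(1, -45, 45),
                  runif(1, 0.8, 1.2))
    pts <- matrix(runif(20, -100, 100), ncol = 2)
    via_compose <- apply_affine(compose_affine(a, b), pts)
    via_seq <- apply_affine(a, apply_affine(b, pts))
    expect_lt(max(abs(via_compose - via_seq)), 1e-6)
  }
})

test_that("a transform composed with its inverse is the identity", {
  set.seed(7)
  for (rep in 1:20) {
    a <- affine2d(runif(1, -30, 30), runif(1, -30, 30), runif(1, -90, 90),
                  runif(1, 0.7, 1.4))
    id <- compose_affine(a, invert_affine(a))
    expect_lt(max(abs(unlist(id[c("tx", "ty", "theta")]))), 1e-9)
    expect_lt(abs(id$s - 1), 1e-9)
  }
})

test_that("invalid parameters are rejected", {
  expect_error(affine2d(s = 0), "positive")
  expect_error(affine2d(s = -1), "positive")
  expect_error(affine2d(tx = Inf), "finite")
})

test_that("warping by the identity leaves an image unchanged", {
  img <- matrix(runif(64 * 48), 64, 48)
  expect_equal(warp_image(img, affine2d()), img)
  expect_equal(warp_image(img, affine2d(), interp = "nearest"), img)
})

test_that("warping a shifted image moves content by the stated translation", {
  img <- matrix(0, 32, 32); img[10:14, 8:12] <- 1
  out <- warp_image(img, affine2d(tx = 5, ty = 3), interp = "nearest")
  expect_equal(out[13:17, 13:17], img[10:14, 8:12])
})

test_that("tidy() returns the four parameters", {
  td <- tidy(affine2d(1, 2, 3, 1.1))
  expect_equal(unlist(td), c(tx = 1, ty = 2, theta = 3, s = 1.1))
})
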