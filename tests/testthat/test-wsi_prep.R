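test_that("the operator chain recovers a known biopsy rotation", {
  sl <- fx_rect_slide(17)
  roi <- detect_roi(sl)
  expect_lt(abs(roi$rotated_rect$angle_deg - 17), 1)
  # width >= height convention resolves the 90-degree ambiguity
  expect_gte(roi$rotated_rect$width, roi$rotated_rect$height)
  # the chain is deterministic
  roi2 <- detect_roi(sl)
  expect_identical(roi$roi_mask, roi2$roi_mask)
  expect_identical(roi$rotated_rect, roi2$rotated_rect)
})

test_that("a blank slide raises an empty-slide error", {
  expect_error(detect_roi(array(1, c(64, 64, 3))), "empty slide")
})

test_that("the largest bounding-box component wins over small debris", {
  img <- matrix(1, 128, 128)
  img[20:119, 10:109] <- 0.3   # biopsy
  img[5:12, 120:124] <- 0.3    # debris
  roi <- detect_roi(array(rep(img, 3), c(128, 128, 3)))
  bb <- roi$bounding_box
  expect_gte(bb["w"], 95)
  expect_gte(bb["h"], 95)
  expect_lt(bb["x"], 20)
})

test_that("downsampled export reports the correct pixel ratio", {
  sl <- fx_rect_slide(17)
  roi <- detect_roi(sl)
  we <- coarse_align_and_export(sl, roi, pixel_ratio_um = 0.121267,
                                downsample = 8.0)
  expect_equal(unname(we$pixel_ratio_um[1]), 0.970136)
  # physical size conserved within one input pixel per axis
  out_dim <- dim(we$image)[1:2]
  expect_lt(abs(out_dim[1] * we$pixel_ratio_um[1] - we$crop["h"] * 0.121267),
            8 * 0.121267 + 1e-9)
  expect_lt(abs(out_dim[2] * we$pixel_ratio_um[2] - we$crop["w"] * 0.121267),
            8 * 0.121267 + 1e-9)
})

test_that("upright slides pass through the export almost unchanged", {
  img <- matrix(1, 120, 120)
  img[31:90, 21:100] <- 0.2
  sl <- array(rep(img, 3), c(120, 120, 3))
  roi <- detect_roi(sl)
  expect_lt(abs(roi$rotated_rect$angle_deg), 1)
  we <- coarse_align_and_export(sl, roi, pixel_ratio_um = 1,
                                target_shape = unname(roi$bounding_box[c("h", "w")]))
  expect_equal(unname(we$downsample), c(1, 1), tolerance = 0.2)
})

test_that("binary masks survive bicubic scaling with threshold 128", {
  all_on <- trabekit:::cpp_resize(matrix(255, 64, 64), 32, 32, "bicubic") > 128
  all_off <- trabekit:::cpp_resize(matrix(0, 64, 64), 32, 32, "bicubic") > 128
  expect_true(all(all_on))
  expect_false(any(all_off))
})

test_that("min_area_rect reports angles in (-90, 90] with width >= height", {
  set.seed(3)
  for (ang in c(-70, -30, 0, 17, 45, 89)) {
    th <- ang * pi / 180
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    pts <- t(replicate(200, runif(1, -50, 50) * u + runif(1, -20, 20) * v))
    r <- min_area_rect(pts)
    expect_gte(r$width, r$height)
    expect_gt(r$angle_deg, -90)
    expect_lte(r$angle_deg, 90)
    diff_ang <- min(abs(r$angle_deg - ang), abs(r$angle_deg - ang + 180),
                    abs(r$angle_deg - ang - 180))
    expect_lt(diff_ang, 5)
  }
})
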