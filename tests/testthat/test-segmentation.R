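test_that("tiling covers the image with the stated stride and full-size tiles", {
  ts1 <- tile_image(matrix(0, 512, 512))
  expect_equal(nrow(ts1$origins), 1L)
  expect_equal(unlist(ts1$origins[1, ]), c(row = 1, col = 1))
  ts2 <- tile_image(matrix(0, 960, 512))
  expect_equal(sort(unique(ts2$origins$row)), c(1, 449))
  expect_equal(unique(ts2$origins$col), 1)
  # all tiles exactly tile-sized, adjacent origins differ by 512 - 64
  expect_true(all(vapply(ts2$tiles, function(t) all(dim(t) == c(512, 512)),
                         logical(1))))
})

test_that("small images are reflect-padded up to one tile", {
  ts <- tile_image(matrix(1:100, 10, 10), tile = 16, overlap = 4)
  expect_equal(dim(ts$tiles[[1]]), c(16, 16))
  expect_equal(ts$parent_shape, c(10, 10))
})

test_that("stitching tiles of an image reproduces it exactly", {
  img <- matrix(runif(960 * 700), 960, 700)
  ts <- tile_image(img, 512, 64)
  expect_equal(stitch_tiles(ts$tiles, ts), img)
})

test_that("class weights follow the inverse-frequency formula", {
  balanced <- matrix(rep(0:2, each = 100), 10)
  expect_equal(unname(compute_class_weights(balanced)), rep(1, 3))
  skewed <- matrix(c(rep(0, 70), rep(1, 10), rep(2, 20)), 10)
  expect_equal(unname(compute_class_weights(skewed)),
               c(1 / (3 * 0.7), 1 / (3 * 0.1), 1 / (3 * 0.2)),
               tolerance = 1e-12)
  # doubling the dataset leaves weights unchanged
  expect_equal(compute_class_weights(list(skewed, skewed)),
               compute_class_weights(skewed))
  no_graft <- matrix(rep(0:1, 50), 10)
  expect_error(compute_class_weights(no_graft), "graft")
})

test_that("ensemble prediction averages stub models and stitches seams", {
  const_stub <- function(p) function(tile) {
    out <- array(0, c(dim(tile)[1:2], 3))
    for (k in 1:3) out[, , k] <- p[k]
    out
  }
  img <- array(runif(64 * 100 * 3), c(64, 100, 3))
  p1 <- predict_ensemble(img, list(const_stub(c(1, 0, 0))), tile = 32, overlap = 8)
  expect_true(all(p1[, , 1] == 1))
  p2 <- predict_ensemble(img, list(const_stub(c(1, 0, 0)), const_stub(c(0, 1, 0))),
                         tile = 32, overlap = 8)
  expect_true(all(abs(p2[, , 1] - 0.5) < 1e-12))
  expect_true(all(abs(p2[, , 2] - 0.5) < 1e-12))
  # a seam between two tiles whose outputs differ averages in the overlap
  gradient_stub <- function(tile) {
    out <- array(0, c(dim(tile)[1:2], 3))
    out[, , 1] <- mean(tile)  # depends on tile content
    out[, , 2] <- 1 - mean(tile)
    out[, , 3] <- 0
    out + 1e-9
  }
  img2 <- array(0, c(32, 56, 3)); img2[, 29:56, ] <- 1
  ts <- tile_image(img2, 32, 8)
  pm <- predict_ensemble(img2, list(gradient_stub), tile = 32, overlap = 8)
  t1 <- gradient_stub(ts$tiles[[1]]); t2 <- gradient_stub(ts$tiles[[2]])
  ov <- (t1[1, 32, 1] + t2[1, 8, 1]) / 2
  expect_equal(pm[1, 32, 1], ov / (ov + (1 - ov)), tolerance = 1e-6)
})

test_that("probabilities stay normalized through ensembling and postprocessing", {
  set.seed(2)
  pm <- array(runif(40 * 40 * 3), c(40, 40, 3))
  tot <- pm[, , 1] + pm[, , 2] + pm[, , 3]
  for (k in 1:3) pm[, , k] <- pm[, , k] / tot
  post <- postprocess_probabilities(pm, filter_size = 8)
  sums <- post$prob_map[, , 1] + post$prob_map[, , 2] + post$prob_map[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("a constant probability map passes the bilateral filter unchanged", {
  pm <- array(rep(c(0.2, 0.5, 0.3), each = 100), c(10, 10, 3))
  post <- postprocess_probabilities(pm, filter_size = 8)
  expect_equal(post$prob_map, pm, tolerance = 1e-9)
  expect_true(all(post$class_mask == 1L))
})

test_that("exact probability ties resolve by the class priority", {
  pm <- array(0, c(2, 2, 3))
  pm[, , 1] <- 0.4; pm[, , 2] <- 0.4; pm[, , 3] <- 0.2
  post <- postprocess_probabilities(pm, filter_size = 2)
  expect_true(all(post$class_mask == 1L))  # bone wins its ties
  pm2 <- array(0, c(2, 2, 3))
  pm2[, , 1] <- 0.4; pm2[, , 2] <- 0.2; pm2[, , 3] <- 0.4
  post2 <- postprocess_probabilities(pm2, filter_size = 2)
  expect_true(all(post2$class_mask == 2L))  # graft beats non-mineralized
})

test_that("bilateral smoothing removes salt noise without moving the class edge", {
  pm <- array(0, c(40, 40, 3))
  pm[, 1:20, 2] <- 0.9; pm[, 1:20, 1] <- 0.1
  pm[, 21:40, 1] <- 0.9; pm[, 21:40, 2] <- 0.1
  # one soft network artifact inside the bone side (mildly flipped, as
  # ensemble artifacts are; a hard 0.9 outlier would be an edge to preserve)
  pm[20, 10, 1] <- 0.55; pm[20, 10, 2] <- 0.45
  post <- postprocess_probabilities(pm, filter_size = 8, sigma_color = 64,
                                    sigma_space = 8)
  expect_equal(post$class_mask[20, 10], 1L)           # noise pixel removed
  expect_true(all(post$class_mask[, 1:19] == 1L))     # edge position unmoved
  expect_true(all(post$class_mask[, 22:40] == 0L))
  # a Gaussian blur control of the same width displaces mass across the edge
  g <- trabekit:::cpp_gauss_blur2d(pm[, , 2], 4)
  expect_gt(max(abs(g[, 21] - pm[, 21, 2])), 0.2)
})

test_that("the learning-rate schedule drops by 10x after the stall patience", {
  cfg <- unet_config("full")
  # no improvement after epoch 30
  losses <- c(seq(1, 0.5, length.out = 30), rep(0.5, 70))
  lr <- lr_schedule_trace(losses, cfg)
  expect_equal(lr[1], 1e-3)
  expect_lte(lr[61], 1e-4)
  expect_gte(min(lr), cfg$lr_floor)
})

test_that("fold partitions are equal-sized, disjoint and seed-deterministic", {
  cfg <- unet_config("tiny", folds = 5L, seed = 11L)
  n <- 40
  f1 <- trabekit:::with_seed(cfg$seed, sample(rep(seq_len(cfg$folds),
                                                  length.out = n)))
  f2 <- trabekit:::with_seed(cfg$seed, sample(rep(seq_len(cfg$folds),
                                                  length.out = n)))
  expect_identical(f1, f2)
  expect_true(all(table(f1) == 8))
})

test_that("network geometry: pooling halves the tile down to the bottleneck", {
  tiny <- unet_init(unet_config("tiny"), seed = 1)
  expect_equal(unet_bottleneck_shape(tiny), c(8L, 8L))
  expect_error(unet_config("tiny", tile = 30L), "not divisible")
})

test_that("backpropagation matches finite differences", {
  cfg <- unet_config("tiny", tile = 16L, base_channels = 4L, dropout_rate = 0)
  model <- unet_init(cfg, seed = 9)
  set.seed(2)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
  w <- compute_class_weights(list(matrix(y, 16)))
  fwd <- trabekit:::unet_forward(model, x, train = TRUE)
  l <- trabekit:::weighted_ce(fwd$probs, y, w)
  grads <- trabekit:::unet_backward(fwd, l$dlogits)
  eps <- 1e-5
  for (path in list(c("out", "w"), c("enc", "1", "w1"), c("bott", "w1"),
                    c("dec", "1", "wt"), c("dec", "2", "w2"))) {
    g_ana <- trabekit:::leaf_get(grads, path)
    i <- length(g_ana) %/% 2 + 1
    perturb <- function(delta) {
      m2 <- model
      core <- unclass(m2)[c("enc", "bott", "dec", "out")]
      v <- trabekit:::leaf_get(core, path); v[i] <- v[i] + delta
      core <- trabekit:::leaf_set(core, path, v)
      for (nm in names(core)) m2[[nm]] <- core[[nm]]
      f <- trabekit:::unet_forward(m2, x, train = TRUE)
      trabekit:::weighted_ce(f$probs, y, w)$loss
    }
    g_num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    expect_lt(abs(g_ana[i] - g_num), 1e-6)
  }
})

test_that("a short training run learns the stain classes", {
  d <- fx_stain_tiles(seed = 1, n_tiles = 16)
  cfg <- unet_config("tiny", epochs = 12L, seed = 1L)
  m <- train_unet(d$tiles, d$masks, idx_train = 1:13, idx_val = 14:16, cfg)
  expect_gte(tail(m$history$val_accuracy, 1), 0.85)
  expect_true(all(diff(m$history$epoch) == 1))
})
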