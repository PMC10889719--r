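# Shared phantom fixtures, built once per test run.  Sizes are chosen so the
# whole suite stays desk-scale; every fixture is deterministic.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# 64^3 trabecular phantom at microCT-like voxels
fx_phantom <- function() fixture("phantom", function() {
  generate_trabecular_volume(phantom_spec(
    grid_shape = c(64, 64, 64), voxel_size_um = 11, target_bvtv = 0.3,
    correlation_length_um = 44, graft_fraction = 0.25, seed = 7))
})

fx_ct <- function() fixture("ct", function() {
  simulate_microct(fx_phantom()$labeled, blur_sigma_vox = 0.7, noise_sd = 0.05,
                   seed = 2)
})

# jitter-free stack (ground-truth transforms are the identity)
fx_stack_clean <- function() fixture("stack_clean", function() {
  simulate_histology_stack(fx_phantom()$labeled,
                           histology_sim_spec(slice_thickness_um = 11, seed = 4))
})

# standard-jitter stack
fx_stack_jitter <- function() fixture("stack_jitter", function() {
  simulate_histology_stack(fx_phantom()$labeled, histology_sim_spec(
    slice_thickness_um = 11, max_rotation_deg = 10, max_translation_px = 20,
    max_scale_dev = 0.03, dropout_prob = 0, stain_noise_sd = 0.02, seed = 3))
})

# stain tiles at histology-like pixel scale (class maps upsampled 4x before
# staining, emulating sections scanned much finer than the CT voxel)
fx_stain_tiles <- function(seed, n_tiles = 36) {
  cfg <- unet_config("tiny")
  ph <- fx_phantom()
  tiles <- list(); masks <- list()
  set.seed(seed + 100)
  for (k in c(10, 30, 50)) {
    si <- stain_image(ph$labeled$voxels[, , k], noise_sd = 0.02, upsample = 4L)
    ts <- tile_image(si$image, cfg$tile, cfg$overlap)
    tm <- tile_image(si$mask, cfg$tile, cfg$overlap)
    tiles <- c(tiles, ts$tiles)
    masks <- c(masks, tm$tiles)
  }
  keep <- sample(length(tiles), n_tiles)
  list(tiles = tiles[keep], masks = masks[keep])
}

# synthetic slide: one filled rotated rectangle on a white field
fx_rect_slide <- function(angle, n = 256, cx = 130, cy = 120, hw = 60, hh = 30) {
  th <- angle * pi / 180
  jj <- matrix(rep(1:n, each = n), n, n)  # jj[i, j] = j
  ii <- matrix(rep(1:n, times = n), n, n) # ii[i, j] = i
  u <- (jj - cx) * cos(th) + (ii - cy) * sin(th)
  v <- -(jj - cx) * sin(th) + (ii - cy) * cos(th)
  img <- matrix(1, n, n)
  img[abs(u) <= hw & abs(v) <= hh] <- 0.2
  array(rep(img, 3), c(n, n, 3))
}
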