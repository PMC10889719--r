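#' Specification of a synthetic trabecular phantom
#'
#' Describes a random trabecular network: a smooth Gaussian random field is
#' thresholded at the quantile that yields the requested mineralized volume
#' fraction, and a fraction of the mineralized phase is relabelled as residual
#' graft material in contiguous blobs.
#'
#' @param grid_shape Integer vector of 3 voxel counts, each at least 32.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param target_bvtv Target mineralized volume fraction, strictly in (0, 1).
#' @param correlation_length_um Spatial correlation length of the random
#'   field, in micrometres; sets the characteristic strut/pore scale.
#' @param graft_fraction Fraction of mineralized voxels assigned to the graft
#'   class, in `[0, 1)`.
#' @param seed Integer seed; a fixed seed gives byte-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size_um = 11,
                         target_bvtv = 0.3, correlation_length_um = 44,
                         graft_fraction = 0.25, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  if (any(grid_shape < 32)) abort("phantom_spec: each grid dimension must be >= 32")
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0)
    abort("phantom_spec: voxel_size_um must be positive")
  if (!is.finite(target_bvtv) || target_bvtv <= 0 || target_bvtv >= 1)
    abort("phantom_spec: target_bvtv must lie strictly in (0, 1)")
  if (correlation_length_um <= 0) abort("phantom_spec: correlation_length_um must be positive")
  if (graft_fraction < 0 || graft_fraction >= 1)
    abort("phantom_spec: graft_fraction must lie in [0, 1)")
  corr_vox <- correlation_length_um / voxel_size_um
  if (min(grid_shape) < 2 * corr_vox)
    abort(sprintf(paste0("phantom_spec: grid too small to host one correlation length ",
                         "(need min dimension >= %.0f voxels for correlation_length_um = %g ",
                         "at voxel_size_um = %g)"),
                  ceiling(2 * corr_vox), correlation_length_um, voxel_size_um))
  structure(list(grid_shape = grid_shape, voxel_size_um = voxel_size_um,
                 target_bvtv = target_bvtv,
                 correlation_length_um = correlation_length_um,
                 graft_fraction = graft_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic trabecular volume
#'
#' White Gaussian noise is smoothed with a Gaussian kernel of scale
#' `correlation_length_um / voxel_size_um` voxels and thresholded at the
#' empirical quantile that makes the mineralized fraction equal
#' `target_bvtv`; with a continuous field the achieved fraction matches the
#' target to well within 0.5 percentage points by construction.  A
#' `graft_fraction` of the mineralized voxels, selected as contiguous blobs of
#' a second, independent smooth field, is relabelled as graft.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `labeled` (a [labeled_volume()] with classes
#'   0/1/2), `grayscale` (the underlying smooth field, rescaled to `[0, 1]`)
#'   and `mineral_mask` (logical array, the mineralized phase).
#' @export
generate_trabecular_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sigma <- spec$correlation_length_um / spec$voxel_size_um / 2
  with_seed(spec$seed, {
    field <- array(rnorm(prod(d)), d)
    field <- cpp_blur3d(field, sigma)
    thr <- quantile(field, 1 - spec$target_bvtv, names = FALSE)
    mineral <- field > thr
    cls <- array(0L, d)
    cls[mineral] <- 1L
    if (spec$graft_fraction > 0) {
      gfield <- cpp_blur3d(array(rnorm(prod(d)), d), sigma)
      gthr <- quantile(gfield[mineral], 1 - spec$graft_fraction, names = FALSE)
      cls[mineral & (gfield > gthr)] <- 2L
    }
    gs <- (field - min(field)) / (max(field) - min(field))
    list(labeled = labeled_volume(cls, spec$voxel_size_um, frame = "phantom"),
         grayscale = gs,
         mineral_mask = mineral)
  })
}

#' Simulate a microCT rendering of a labelled volume
#'
#' Mineralized classes (bone and graft are both radiopaque) are mapped to a
#' high intensity and non-mineralized tissue to a low intensity; the two-level
#' volume is Gaussian-blurred (partial-volume effect) and corrupted with
#' additive Gaussian noise, then clipped to `[0, 1]`.
#'
#' @param labeled A [labeled_volume()].
#' @param blur_sigma_vox Gaussian blur standard deviation in voxels (>= 0).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise.
#' @param levels Intensities for (non-mineralized, mineralized); defaults
#'   `c(0.15, 0.85)` leave headroom before clipping.
#' @return A 3D numeric array in `[0, 1]` with the input's dimensions.
#' @export
simulate_microct <- function(labeled, blur_sigma_vox = 0.7, noise_sd = 0.05,
                             seed = 1L, levels = c(0.15, 0.85)) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (blur_sigma_vox < 0 || noise_sd < 0)
    abort("simulate_microct: blur_sigma_vox and noise_sd must be non-negative")
  vol <- array(levels[1], dim(labeled$voxels))
  vol[labeled$voxels == 1L | labeled$voxels == 2L] <- levels[2]
  if (blur_sigma_vox > 0) vol <- cpp_blur3d(vol, blur_sigma_vox)
  if (noise_sd > 0) {
    vol <- with_seed(seed, vol + array(rnorm(length(vol), sd = noise_sd), dim(vol)))
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  vol
}

#' Default stain colours for the three tissue classes
#'
#' Fixed test-fixture hues loosely evoking an H&E-stained, grafted biopsy:
#' eosin-pink bone, violet graft particles, pale-pink non-mineralized tissue.
#' These are fixture colours, not a chemical stain model.
#'
#' @return A 3x3 matrix; rows = classes (non-mineralized, bone, graft),
#'   columns = RGB in `[0, 1]`.
#' @export
stain_palette <- function() {
  matrix(c(0.95, 0.85, 0.88,   # 0 non-mineralized: pale pink
           0.85, 0.40, 0.50,   # 1 bone: eosin pink
           0.50, 0.35, 0.70),  # 2 graft: violet
         nrow = 3, byrow = TRUE,
         dimnames = list(c("nonmineralized", "bone", "graft"), c("r", "g", "b")))
}

#' Stain a class map into an RGB image
#'
#' Maps the three tissue classes to the fixture stain hues of
#' [stain_palette()] and adds Gaussian RGB noise.  Used by
#' [simulate_histology_stack()]; exported so segmentation fixtures can be
#' built at an arbitrary pixel scale (real stained sections are scanned at
#' roughly ten times the microCT resolution, so a class map is typically
#' upsampled before staining when emulating them).
#'
#' @param class_map Integer matrix with values 0/1/2.
#' @param noise_sd Additive RGB noise standard deviation.
#' @param upsample Integer nearest-neighbour upsampling factor applied to the
#'   class map before staining.
#' @return List: `image` (H x W x 3 in `[0, 1]`), `mask` (the possibly
#'   upsampled class map).
#' @export
stain_image <- function(class_map, noise_sd = 0, upsample = 1L) {
  if (upsample > 1) {
    idx_r <- rep(seq_len(nrow(class_map)), each = upsample)
    idx_c <- rep(seq_len(ncol(class_map)), each = upsample)
    class_map <- class_map[idx_r, idx_c]
  }
  pal <- stain_palette()
  d <- dim(class_map)
  rgb <- array(0, c(d, 3))
  for (ch in 1:3) {
    plane <- matrix(pal[class_map + 1L, ch], d[1], d[2])
    if (noise_sd > 0)
      plane <- plane + matrix(rnorm(length(plane), sd = noise_sd), d[1], d[2])
    rgb[, , ch] <- plane
  }
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  list(image = rgb, mask = class_map)
}

#' Specification of the simulated histology sectioning process
#'
#' @param slice_thickness_um Section thickness in micrometres (default 5, the
#'   usual microtome setting for decalcified bone).
#' @param max_rotation_deg,max_translation_px,max_scale_dev Per-slide jitter
#'   bounds: rotation is drawn uniformly in `[-max_rotation_deg,
#'   max_rotation_deg]`, each translation component in `[-max_translation_px,
#'   max_translation_px]`, and scale in `[1 - max_scale_dev, 1 +
#'   max_scale_dev]`.
#' @param dropout_prob Probability that a slide is "torn" and discarded.
#' @param stain_noise_sd Additive RGB noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `histology_sim_spec`.
#' @export
histology_sim_spec <- function(slice_thickness_um = 5, max_rotation_deg = 0,
                               max_translation_px = 0, max_scale_dev = 0,
                               dropout_prob = 0, stain_noise_sd = 0, seed = 1L) {
  if (!is.finite(slice_thickness_um) || slice_thickness_um <= 0)
    abort("histology_sim_spec: slice_thickness_um must be positive")
  bounds <- c(max_rotation_deg, max_translation_px, max_scale_dev)
  if (any(!is.finite(bounds)) || any(bounds < 0))
    abort("histology_sim_spec: jitter bounds must be finite and non-negative")
  if (max_scale_dev >= 1) abort("histology_sim_spec: max_scale_dev must be < 1")
  if (dropout_prob < 0 || dropout_prob >= 1)
    abort("histology_sim_spec: dropout_prob must lie in [0, 1)")
  if (stain_noise_sd < 0) abort("histology_sim_spec: stain_noise_sd must be >= 0")
  structure(list(slice_thickness_um = slice_thickness_um,
                 max_rotation_deg = max_rotation_deg,
                 max_translation_px = max_translation_px,
                 max_scale_dev = max_scale_dev,
                 dropout_prob = dropout_prob,
                 stain_noise_sd = stain_noise_sd,
                 seed = as.integer(seed)),
            class = "histology_sim_spec")
}

#' Simulate a stained, jittered serial-section stack from a labelled volume
#'
#' The volume is sectioned along its third axis at `slice_thickness_um`
#' intervals (z index = `floor(z_position / voxel_size)`); each retained
#' section is stain-coloured with [stain_palette()], perturbed with additive
#' RGB noise, and warped by a random in-plane [affine2d()] drawn within the
#' jitter bounds.  Random slides are dropped ("torn") with probability
#' `dropout_prob`.  The ground truth records, per slide, the applied
#' transform, the source z index, and the jittered per-pixel class mask.
#'
#' Each section is laid on a canvas larger than the volume cross-section (a
#' real slide always carries the whole biopsy with a margin of empty slide
#' around it), so jitter never pushes tissue out of frame; the margin is
#' sized automatically from the jitter bounds unless given.
#'
#' @param labeled A [labeled_volume()] with isotropic in-plane spacing.
#' @param sim A [histology_sim_spec()].
#' @param margin_px Canvas margin around the section in pixels; `NULL` (the
#'   default) sizes it so the configured jitter cannot clip tissue.
#' @return A list of class `histology_stack` with elements
#'   * `slides`: list of H x W x 3 RGB arrays (retained slides only),
#'   * `masks`: list of H x W integer class masks, jittered like the slides,
#'   * `truth`: tibble with `slide_id`, `z_index`, `tx`, `ty`, `theta`, `s`,
#'     `dropped` (all sections, including dropped ones),
#'   * `clean_masks`: list of unjittered class maps (retained slides),
#'   * `mineral_volume`: logical array, the mineralized ground-truth volume,
#'   * `pixel_ratio_um`: in-plane pixel size of the slides.
#' @export
simulate_histology_stack <- function(labeled, sim, margin_px = NULL) {
  stopifnot(inherits(labeled, "labeled_volume"), inherits(sim, "histology_sim_spec"))
  vox <- labeled$voxels
  d <- dim(vox)
  if (is.null(margin_px)) {
    half_diag <- sqrt(sum(d[1:2]^2)) / 2
    margin_px <- ceiling(sim$max_translation_px +
                           half_diag * (sin(sim$max_rotation_deg * pi / 180) +
                                          sim$max_scale_dev) + 2)
  }
  margin_px <- as.integer(margin_px)
  canvas <- d[1:2] + 2L * margin_px
  vsz <- labeled$spacing_um[3]
  ratio <- sim$slice_thickness_um / vsz
  if (abs(ratio - round(ratio)) > 1e-8)
    inform(sprintf(paste0("simulate_histology_stack: slice thickness %g um is not a ",
                          "multiple of the voxel size %g um; sections are assigned to ",
                          "the nearest-below voxel plane (z index = floor(z/voxel))"),
                   sim$slice_thickness_um, vsz))
  z_pos <- seq(0, (d[3] - 1) * vsz, by = sim$slice_thickness_um)
  z_idx <- pmin(floor(z_pos / vsz) + 1L, d[3])  # 1-based planes
  pal <- stain_palette()
  with_seed(sim$seed, {
    n <- length(z_idx)
    tx <- runif(n, -sim$max_translation_px, sim$max_translation_px)
    ty <- runif(n, -sim$max_translation_px, sim$max_translation_px)
    th <- runif(n, -sim$max_rotation_deg, sim$max_rotation_deg)
    s <- runif(n, 1 - sim$max_scale_dev, 1 + sim$max_scale_dev)
    dropped <- runif(n) < sim$dropout_prob
    if (all(dropped))
      abort("simulate_histology_stack: dropout removed every slide; lower dropout_prob")
    truth <- tibble(slide_id = seq_len(n), z_index = as.integer(z_idx),
                    tx = tx, ty = ty, theta = th, s = s, dropped = dropped)
    slides <- list(); masks <- list(); clean <- list()
    for (i in seq_len(n)) {
      if (dropped[i]) next
      cls <- matrix(0L, canvas[1], canvas[2])
      cls[margin_px + seq_len(d[1]), margin_px + seq_len(d[2])] <- vox[, , z_idx[i]]
      a <- affine2d(tx[i], ty[i], th[i], s[i])
      rgb <- array(0, c(canvas[1], canvas[2], 3))
      for (ch in 1:3) {
        plane <- matrix(pal[cls + 1L, ch], canvas[1], canvas[2])
        if (sim$stain_noise_sd > 0)
          plane <- plane + matrix(rnorm(length(plane), sd = sim$stain_noise_sd),
                                  canvas[1], canvas[2])
        rgb[, , ch] <- cpp_warp_affine(plane, a$tx, a$ty, a$theta, a$s,
                                       "bilinear", pal[1L, ch])
      }
      rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
      m <- cpp_warp_affine(matrix(as.numeric(cls), canvas[1], canvas[2]),
                           a$tx, a$ty, a$theta, a$s, "nearest", 0)
      key <- as.character(i)
      slides[[key]] <- rgb
      masks[[key]] <- matrix(as.integer(m), canvas[1], canvas[2])
      clean[[key]] <- cls
    }
    structure(list(slides = slides, masks = masks, truth = truth,
                   clean_masks = clean,
                   mineral_volume = vox == 1L | vox == 2L,
                   pixel_ratio_um = labeled$spacing_um[1],
                   margin_px = margin_px),
              class = "histology_stack")
  })
}

#' @export
print.histology_stack <- function(x, ...) {
  cat(sprintf("<histology_stack> %d retained slides (%d dropped), %s px, %.3g um/px\n",
              length(x$slides), sum(x$truth$dropped),
              paste(dim(x$slides[[1]])[1:2], collapse = " x "), x$pixel_ratio_um))
  invisible(x)
}

# ---- analytic lattice phantoms (known-geometry fixtures for morphometry) ----

#' Analytic binary phantoms with known geometry
#'
#' Deterministic lattice volumes whose morphometric parameters have closed
#' forms: a half-space slab, a voxelized solid ball, a hollow shell (ball with
#' a concentric cavity), and a stack of parallel plates.  These complement the
#' random-field phantom wherever a test needs an analytic answer.
#'
#' @param n Cubic grid edge length in voxels.
#' @param spacing_um Voxel size in micrometres.
#' @return A [binary_volume()].
#' @name analytic_phantoms
NULL

#' @rdname analytic_phantoms
#' @param fill Fraction of planes filled along the third axis.
#' @export
phantom_slab <- function(n = 64, fill = 0.5, spacing_um = 1) {
  v <- array(FALSE, c(n, n, n))
  v[, , seq_len(round(fill * n))] <- TRUE
  binary_volume(v, spacing_um)
}

#' @rdname analytic_phantoms
#' @param r Ball radius in voxels.
#' @export
phantom_ball <- function(n = 51, r = 20, spacing_um = 1) {
  co <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  binary_volume(array(r2 <= r^2, c(n, n, n)), spacing_um)
}

#' @rdname analytic_phantoms
#' @param r_outer,r_inner Outer and cavity radii in voxels.
#' @export
phantom_hollow_shell <- function(n = 51, r_outer = 20, r_inner = 10, spacing_um = 1) {
  stopifnot(r_inner < r_outer)
  co <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  binary_volume(array(r2 <= r_outer^2 & r2 > r_inner^2, c(n, n, n)), spacing_um)
}

#' @rdname analytic_phantoms
#' @param thickness,gap Plate thickness and inter-plate gap in voxels; the
#'   stack starts and ends with a half gap so the volume borders are symmetry
#'   planes of the lattice (matching the mirror assumption the thickness
#'   transform makes at the field-of-view border).
#' @export
phantom_plates <- function(n = 60, thickness = 5, gap = 10, spacing_um = 1) {
  period <- thickness + gap
  p <- seq_len(n) - 1
  half <- floor(gap / 2)
  in_plate <- (p %% period) >= half & (p %% period) < half + thickness
  v <- array(FALSE, c(n, n, n))
  v[, , in_plate] <- TRUE
  binary_volume(v, spacing_um)
}
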