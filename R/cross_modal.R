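# Final alignment: in-silico slicing of the microCT volume, per-slide
# matched-keypoint profiles with bell-curve peak fitting, cross-modal
# registration and assembly of the labelled reconstruction on the CT grid.

#' Slice a 3D volume in silico
#'
#' Resamples a CT volume into planar sections along a given cut normal, the
#' same plane the physical sectioning used.  Axis-aligned cuts at native
#' spacing return the raw voxel planes exactly; oblique cuts are sampled
#' trilinearly.
#'
#' @param vol 3D numeric array (e.g. from [simulate_microct()]).
#' @param voxel_size_um Isotropic voxel size of `vol`.
#' @param normal Cut normal in voxel coordinates (default the third axis).
#' @param slice_spacing_um Distance between consecutive slices.
#' @param pixel_size_um In-plane sample spacing of each slice.
#' @param out_shape Output (rows, cols) per slice; defaults to a frame
#'   covering the volume's projection.
#' @return List of class `ct_stack`: `slices` (list of matrices),
#'   `positions_um` (distance of each slice along the normal),
#'   `pixel_size_um`, `slice_spacing_um`, `normal`.
#' @export
slice_volume <- function(vol, voxel_size_um, normal = c(0, 0, 1),
                         slice_spacing_um = voxel_size_um,
                         pixel_size_um = voxel_size_um, out_shape = NULL) {
  d <- dim(vol)
  if (length(d) != 3) abort("slice_volume: `vol` must be a 3D array")
  nrm <- normal / sqrt(sum(normal^2))
  axis_aligned <- isTRUE(all.equal(abs(nrm), c(0, 0, 1), tolerance = 1e-9))
  if (axis_aligned && isTRUE(all.equal(slice_spacing_um, voxel_size_um)) &&
      isTRUE(all.equal(pixel_size_um, voxel_size_um)) && is.null(out_shape)) {
    ks <- if (nrm[3] > 0) seq_len(d[3]) else rev(seq_len(d[3]))
    slices <- lapply(ks, function(k) vol[, , k])
    return(structure(list(slices = slices,
                          positions_um = (seq_along(ks) - 1) * voxel_size_um,
                          pixel_size_um = voxel_size_um,
                          slice_spacing_um = voxel_size_um, normal = nrm),
                     class = "ct_stack"))
  }
  # orthonormal in-plane basis
  e <- if (abs(nrm[1]) <= abs(nrm[2]) && abs(nrm[1]) <= abs(nrm[3])) c(1, 0, 0)
       else if (abs(nrm[2]) <= abs(nrm[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- pracma_cross(nrm, e); u <- u / sqrt(sum(u^2))
  v <- pracma_cross(nrm, u)
  center <- (d - 1) / 2  # 0-based voxel coords
  half_diag <- sqrt(sum(((d - 1) / 2)^2))
  # slice offsets along the normal covering the volume
  step_vox <- slice_spacing_um / voxel_size_um
  offs <- seq(-half_diag, half_diag, by = step_vox)
  # keep slices whose plane intersects the volume's bounding ball
  px_vox <- pixel_size_um / voxel_size_um
  if (is.null(out_shape)) {
    n_side <- ceiling(2 * half_diag / px_vox) + 1
    out_shape <- c(n_side, n_side)
  }
  out_shape <- as.integer(rep_len(out_shape, 2))
  slices <- list(); pos <- numeric(0)
  for (o in offs) {
    origin <- center + o * nrm -
      ((out_shape[1] - 1) / 2) * v * px_vox - ((out_shape[2] - 1) / 2) * u * px_vox
    sl <- cpp_sample_plane(vol, origin, u * px_vox, v * px_vox,
                           out_shape[1], out_shape[2], NA_real_)
    if (all(is.na(sl))) next
    sl[is.na(sl)] <- 0
    slices[[length(slices) + 1]] <- sl
    pos <- c(pos, o * voxel_size_um)
  }
  if (!length(slices)) abort("slice_volume: cut plane lies outside the volume")
  structure(list(slices = slices, positions_um = pos - min(pos),
                 pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um, normal = nrm),
            class = "ct_stack")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.ct_stack <- function(x, ...) {
  cat(sprintf("<ct_stack> %d slices of %s px, spacing %.3g um, pixel %.3g um\n",
              length(x$slices), paste(dim(x$slices[[1]]), collapse = " x "),
              x$slice_spacing_um, x$pixel_size_um))
  invisible(x)
}

#' Featurize every slice of a CT stack once
#'
#' @param ct_stack A [slice_volume()] result.
#' @param m A [matcher()].
#' @return List of [detect_features()] results, one per slice.
#' @export
featurize_stack <- function(ct_stack, m = matcher(on_gradient = TRUE)) {
  lapply(ct_stack$slices, detect_features, m = m)
}

#' Matched-keypoint profile of one histology slide against a CT stack
#'
#' Counts matched keypoints between the slide and every in-silico CT slice.
#' The matching slice shows up as a peak well above the background count; a
#' bell curve is fitted with [fit_peak()] and its mean determines the matched
#' slice index, which is more noise-robust than the raw argmax.
#'
#' @param slide Grayscale matrix (pre-aligned to the shared coarse frame).
#' @param ct_stack A [slice_volume()] result.
#' @param m A [matcher()]; the default computes descriptors on gradient
#'   magnitude, making the matching robust to the contrast inversion between
#'   stained tissue and CT attenuation.
#' @param ct_features Optional precomputed [featurize_stack()] result.
#' @return Object of class `match_profile`: `counts`, `fit` (A, mu, sigma, b),
#'   `matched_index`, `fallback`, `peak_to_background`.
#' @export
keypoint_profile <- function(slide, ct_stack, m = matcher(on_gradient = TRUE),
                             ct_features = NULL) {
  if (!is.matrix(slide)) slide <- rgb_to_gray(slide)
  ct_features <- ct_features %||% featurize_stack(ct_stack, m)
  fa <- detect_features(slide, m)
  counts <- vapply(ct_features, function(fb) {
    nrow(match_descriptors(fa, fb, m$ratio)$a)
  }, numeric(1))
  if (all(counts == 0))
    abort("keypoint_profile: no correspondence (all matched-keypoint counts are zero)")
  pk <- fit_peak(counts)
  i0 <- which.max(counts)
  far <- abs(seq_along(counts) - i0) > 5
  bg <- if (any(far)) median(counts[far]) else 0
  structure(list(counts = counts, fit = pk$fit, matched_index = pk$matched_index,
                 fallback = pk$fallback,
                 peak_to_background = max(counts) / max(bg, 1)),
            class = "match_profile")
}

#' @export
print.match_profile <- function(x, ...) {
  cat(sprintf("<match_profile> %d slices, matched index %d (mu=%.2f, peak/bg=%.1f%s)\n",
              length(x$counts), x$matched_index,
              if (is.null(x$fit)) NA_real_ else x$fit[["mu"]],
              x$peak_to_background, if (x$fallback) ", argmax fallback" else ""))
  invisible(x)
}

#' @export
tidy.match_profile <- function(x, ...) {
  tb <- tibble(z = seq_along(x$counts), count = x$counts)
  if (!is.null(x$fit)) {
    tb$fitted <- x$fit[["A"]] * exp(-(tb$z - x$fit[["mu"]])^2 / (2 * x$fit[["sigma"]]^2)) +
      x$fit[["b"]]
  }
  tb
}

#' Fit a bell curve to a matched-keypoint profile
#'
#' Least-squares fit of `count(z) = A * exp(-(z - mu)^2 / (2 sigma^2)) + b`,
#' initialized at `(max - median, argmax, 2, median)`.  When the fit diverges
#' (non-finite parameters, or sigma wider than the profile) the argmax is
#' used instead and flagged.
#'
#' @param counts Non-negative numeric vector, length >= 5, some count > 0.
#' @return List: `fit` (named vector A, mu, sigma, b; `NULL` on fallback),
#'   `matched_index` (`round(mu)` clamped to range), `fallback` flag.
#' @export
fit_peak <- function(counts) {
  n <- length(counts)
  if (n < 5) abort("fit_peak: need at least 5 counts")
  if (max(counts) <= 0) abort("fit_peak: all counts are zero")
  z <- seq_len(n)
  start <- list(A = max(counts) - median(counts), mu = which.max(counts),
                sigma = 2, b = median(counts))
  fit <- tryCatch({
    fo <- minpack.lm::nlsLM(counts ~ A * exp(-(z - mu)^2 / (2 * sigma^2)) + b,
                            data = data.frame(z = z, counts = counts),
                            start = start,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- coef(fo)
    p[["sigma"]] <- abs(p[["sigma"]])
    p
  }, error = function(e) NULL)
  ok <- !is.null(fit) && all(is.finite(fit)) && fit[["sigma"]] <= n &&
    fit[["mu"]] >= 0.5 && fit[["mu"]] <= n + 0.5 && fit[["A"]] > 0
  if (!ok) {
    return(list(fit = NULL, matched_index = which.max(counts), fallback = TRUE))
  }
  list(fit = fit[c("A", "mu", "sigma", "b")],
       matched_index = min(max(as.integer(round(fit[["mu"]])), 1L), n),
       fallback = FALSE)
}

#' Register histology slides to their matched CT slices and assemble a volume
#'
#' Each slide's matched CT slice is found from its keypoint profile; the
#' slide is then registered to that slice with the sequential cross-entropy
#' optimizer (run on gradient-magnitude images, which are insensitive to the
#' stain-vs-attenuation contrast inversion), its class mask is warped
#' (nearest-neighbour) into the CT in-plane frame and written at the matched
#' z plane.  If two slides claim the same CT index, the slide with the higher
#' profile peak keeps it and the other is demoted to its best free index.
#' Planes with no slide are marked missing (class 255), or filled by
#' nearest-plane replication when `fill_missing = TRUE`.
#'
#' @param slides List of grayscale matrices (or RGB arrays).
#' @param class_masks List of integer class masks, one per slide.
#' @param ct_stack A [slice_volume()] result with slices on the same pixel
#'   grid as the slides.
#' @param m A [matcher()].
#' @param fill_missing Replicate the nearest occupied plane into missing
#'   planes.
#' @param enforce_monotone Force matched indices to be non-decreasing along
#'   the stack (physical cut order); violations are logged either way.
#' @param refine If `TRUE`, refine each in-plane registration with
#'   [optimize_affine()].
#' @param profiles Optional precomputed list of [keypoint_profile()] results
#'   (one per slide), e.g. cached from an earlier run.
#' @return List of class `reconstruction`: `volume` (a [labeled_volume()] in
#'   the CT frame), `assignments` (tibble: slide, matched_index, peak,
#'   fallback, demoted, monotone_violation), `profiles`.
#' @export
register_and_assemble <- function(slides, class_masks, ct_stack,
                                  m = matcher(on_gradient = TRUE),
                                  fill_missing = FALSE,
                                  enforce_monotone = FALSE, refine = TRUE,
                                  profiles = NULL) {
  if (length(slides) != length(class_masks))
    abort("register_and_assemble: need one class mask per slide")
  n <- length(slides)
  nz <- length(ct_stack$slices)
  ct_features <- featurize_stack(ct_stack, m)
  slides <- lapply(slides, function(s) if (is.matrix(s)) s else rgb_to_gray(s))
  profiles <- profiles %||% lapply(slides, keypoint_profile, ct_stack = ct_stack,
                                   m = m, ct_features = ct_features)
  peak <- vapply(profiles, function(p) max(p$counts), numeric(1))
  want <- vapply(profiles, `[[`, integer(1), "matched_index")
  # collision resolution: higher peak keeps its index
  assigned <- rep(NA_integer_, n)
  taken <- rep(FALSE, nz)
  demoted <- rep(FALSE, n)
  for (i in order(-peak)) {
    k <- want[i]
    if (!taken[k]) { assigned[i] <- k; taken[k] <- TRUE; next }
    demoted[i] <- TRUE
    ord2 <- order(-profiles[[i]]$counts)
    free <- ord2[!taken[ord2]]
    if (!length(free))
      abort("register_and_assemble: more slides than CT slices")
    assigned[i] <- free[1]
    taken[free[1]] <- TRUE
  }
  viol <- c(FALSE, diff(assigned) < 0)
  if (enforce_monotone) assigned <- cummax(assigned)
  d2 <- dim(ct_stack$slices[[1]])
  vox <- array(255L, c(d2[1], d2[2], nz))
  for (i in seq_len(n)) {
    k <- assigned[i]
    ct_sl <- ct_stack$slices[[k]]
    mr <- match_keypoints(slides[[i]], ct_sl, m, features_b = ct_features[[k]])
    # coarse: keypoint similarity from slide coordinates into the CT frame
    # (the slide canvas may be larger than the CT slice)
    a <- estimate_similarity(mr$keypoints_a, mr$keypoints_b,
                             center = image_center(slides[[i]])) %||% affine2d()
    coarse_gray <- warp_to_frame(slides[[i]], a, d2, background = 0)
    b <- affine2d()
    if (refine) {
      b <- tryCatch({
        r <- optimize_affine(gradient_magnitude(coarse_gray), gradient_magnitude(ct_sl),
                             bounds = list(translate = 8, rotate = 3, scale = c(0.95, 1.05)))
        attr(r, "trace") <- NULL
        r
      }, error = function(e) affine2d())
    }
    mk <- warp_to_frame(matrix(as.numeric(class_masks[[i]]), nrow(class_masks[[i]])),
                        a, d2, interp = "nearest", background = 0)
    if (refine) {
      mk <- cpp_warp_affine(mk, b$tx, b$ty, b$theta, b$s, "nearest", 0)
    }
    vox[, , k] <- as.integer(mk)
  }
  missing <- which(!taken)
  if (fill_missing && length(missing) && length(missing) < nz) {
    occupied <- which(taken)
    for (k in missing) {
      nearest <- occupied[which.min(abs(occupied - k))]
      vox[, , k] <- vox[, , nearest]
    }
  }
  vol <- labeled_volume(vox,
                        spacing_um = c(ct_stack$pixel_size_um, ct_stack$pixel_size_um,
                                       ct_stack$slice_spacing_um),
                        frame = "ct",
                        missing_planes = missing)
  list(volume = vol,
       assignments = tibble(slide = seq_len(n), matched_index = assigned,
                            peak = peak,
                            fallback = vapply(profiles, `[[`, logical(1), "fallback"),
                            demoted = demoted, monotone_violation = viol),
       profiles = profiles)
}
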