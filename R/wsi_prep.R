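# Slide pre-processing: biopsy ROI detection and coarse rotated export.

rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  abort("expected a matrix or an H x W x 3 array")
}

# binary morphology on logical matrices, 3x3 square structuring element
shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- max(1, 1 + di):min(nr, nr + di)
  sj <- max(1, 1 + dj):min(nc, nc + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

binary_dilate3 <- function(m, iter = 1) {
  for (t in seq_len(iter)) {
    acc <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- acc | shift_mat(m, di, dj, FALSE)
    }
    m <- acc
  }
  m
}

binary_erode3 <- function(m, iter = 1) {
  for (t in seq_len(iter)) {
    acc <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- acc & shift_mat(m, di, dj, TRUE)
    }
    m <- acc
  }
  m
}

label2d <- function(m, connectivity = 8) {
  a <- array(m, c(dim(m), 1))
  lab <- cpp_label3d(a, if (connectivity == 8) 26L else 6L)
  matrix(lab, nrow(m), ncol(m))
}

fill_holes2d <- function(m) {
  bg <- !m
  lab <- label2d(bg, connectivity = 4)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- setdiff(border_labels, 0L)
  m | (bg & !(lab %in% border_labels))
}

#' Gaussian-weighted adaptive local threshold
#'
#' Local-mean thresholding in the style of imaging toolkits: a pixel is
#' foreground when it is darker than its (Gaussian- or box-weighted) local
#' mean minus an offset, i.e. the inverted-binary reading that picks up dark
#' tissue on a bright slide background.
#'
#' @param gray Grayscale matrix on a 0--255 scale.
#' @param block_size Odd window size in pixels (default 11).
#' @param offset Constant subtracted from the local mean (default 2).
#' @param kind `"gaussian"` (default) or `"mean"` weighting.
#' @return Logical matrix, `TRUE` = foreground (dark).
#' @export
adaptive_threshold <- function(gray, block_size = 11, offset = 2,
                               kind = c("gaussian", "mean")) {
  kind <- match.arg(kind)
  if (block_size %% 2 == 0) abort("adaptive_threshold: block_size must be odd")
  if (kind == "gaussian") {
    sigma <- 0.3 * ((block_size - 1) * 0.5 - 1) + 0.8  # the usual window-to-sigma rule
    local_mean <- cpp_gauss_blur2d(gray, sigma)
  } else {
    local_mean <- box_mean2d(gray, block_size)
  }
  gray < (local_mean - offset)
}

# separable box mean with edge replication
box_mean2d <- function(m, w) {
  pad <- (w - 1) / 2
  smooth_dim <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1, pad), , drop = FALSE], x, x[rep(n, pad), , drop = FALSE])
    cs <- apply(xp, 2, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1):(n + w), , drop = FALSE] - cs[1:n, , drop = FALSE]) / w
  }
  t(smooth_dim(t(smooth_dim(m))))
}

#' Minimum-area (rotated) rectangle of a point set
#'
#' Rotating-calipers search over convex-hull edge directions.  The reported
#' angle lies in `(-90, 90]` with the convention `width >= height`, which
#' resolves the 90-degree ambiguity deterministically.
#'
#' @param pts Two-column matrix of (x, y) coordinates.
#' @return List with `center` (x, y), `width`, `height`, `angle_deg`.
#' @export
min_area_rect <- function(pts) {
  pts <- unique(matrix(as.numeric(pts), ncol = 2))
  if (nrow(pts) < 2) abort("min_area_rect: need at least 2 distinct points")
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  best <- NULL
  edges <- rbind(hull[c(2:nh, 1), ] - hull)
  for (e in seq_len(nh)) {
    v <- edges[e, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-12) next
    ang <- atan2(v[2], v[1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    rot <- hull %*% t(R)
    w <- diff(range(rot[, 1])); h <- diff(range(rot[, 2]))
    area <- w * h
    if (is.null(best) || area < best$area - 1e-9) {
      cen_rot <- c(mean(range(rot[, 1])), mean(range(rot[, 2])))
      cen <- as.numeric(t(R) %*% cen_rot)
      best <- list(area = area, center = cen, width = w, height = h,
                   angle = ang * 180 / pi)
    }
  }
  ang <- best$angle %% 180
  w <- best$width; h <- best$height
  if (w < h) { tmp <- w; w <- h; h <- tmp; ang <- ang + 90 }
  ang <- ((ang + 90) %% 180) - 90
  if (ang == -90) ang <- 90
  list(center = best$center, width = w, height = h, angle_deg = ang)
}

#' Detect the biopsy region of interest on a slide
#'
#' Operator chain: grayscale conversion; Canny edge detection (hysteresis
#' thresholds 100/255 on a 0--255 scale); adaptive local thresholding
#' (window 11, offset 2, inverted binary); the two binary maps are merged by
#' pixelwise OR; 15 iterations of 3x3 dilation followed by 15 of erosion
#' (morphological closing) smooth the contours; connected components are
#' extracted and the component whose axis-aligned bounding rectangle has the
#' largest area is taken as the biopsy.  Ties are broken by larger pixel
#' count, then by the lowest (y, x) box origin.
#'
#' @param slide RGB array (H x W x 3) or grayscale matrix, values in `[0, 1]`
#'   or 0--255.
#' @param canny_low,canny_high Canny hysteresis thresholds (0--255 scale).
#' @param block_size,offset Adaptive-threshold window and offset.
#' @param adaptive_kind `"gaussian"` or `"mean"` local weighting.
#' @param morph_iter Dilation/erosion iteration count.
#' @return List of class `roi_detection`: `bounding_box` (x, y, w, h, 1-based
#'   pixel units), `rotated_rect` (from [min_area_rect()]), `roi_mask`
#'   (logical matrix, the filled contour), `n_pixels`.
#' @export
detect_roi <- function(slide, canny_low = 100, canny_high = 255,
                       block_size = 11, offset = 2,
                       adaptive_kind = c("gaussian", "mean"), morph_iter = 15) {
  adaptive_kind <- match.arg(adaptive_kind)
  gray <- rgb_to_gray(slide)
  if (max(gray) <= 1) gray <- gray * 255
  edges <- cpp_canny(gray, canny_low, canny_high, sigma = 1.0)
  adap <- adaptive_threshold(gray, block_size, offset, adaptive_kind)
  comb <- edges | adap
  comb <- binary_erode3(binary_dilate3(comb, morph_iter), morph_iter)
  lab <- label2d(comb, connectivity = 8)
  ncomp <- max(lab)
  if (ncomp == 0) abort("detect_roi: empty slide (no contour found)")
  stats_list <- vector("list", ncomp)
  for (l in seq_len(ncomp)) {
    idx <- which(lab == l, arr.ind = TRUE)
    bx <- range(idx[, 2]); by <- range(idx[, 1])
    stats_list[[l]] <- c(area = (diff(bx) + 1) * (diff(by) + 1),
                         npix = nrow(idx), y0 = by[1], x0 = bx[1], lab = l)
  }
  st <- do.call(rbind, stats_list)
  ord <- order(-st[, "area"], -st[, "npix"], st[, "y0"], st[, "x0"])
  winner <- st[ord[1], "lab"]
  mask <- lab == winner
  mask <- fill_holes2d(mask)
  idx <- which(mask, arr.ind = TRUE)
  bx <- range(idx[, 2]); by <- range(idx[, 1])
  rect <- min_area_rect(cbind(idx[, 2], idx[, 1]))
  structure(list(bounding_box = c(x = bx[1], y = by[1],
                                  w = diff(bx) + 1, h = diff(by) + 1),
                 rotated_rect = rect,
                 roi_mask = mask,
                 n_pixels = nrow(idx)),
            class = "roi_detection")
}

#' Coarsely align a slide and export a downsampled working image
#'
#' Rotates the image by minus the rotated-rectangle angle so the biopsy lies
#' upright (this rotation is the coarse alignment), crops to the rotated ROI,
#' and resamples bicubically to the target resolution.  Binary masks are
#' scaled the same way and re-binarized at level 128 (of 255).  The exported
#' pixel ratio is the input pixel ratio times the downsample factor.
#'
#' @param image RGB array or grayscale matrix.
#' @param roi A [detect_roi()] result for the same slide.
#' @param pixel_ratio_um Input micrometres per pixel.
#' @param target_shape Output (rows, cols); mutually exclusive with
#'   `downsample`.
#' @param downsample Scalar downsample factor; output shape is the crop shape
#'   divided by it.
#' @param masks Optional named list of logical matrices to carry along.
#' @return List of class `working_image`: `image`, `masks`, `pixel_ratio_um`
#'   (per-axis output ratio), `downsample` (per-axis factors), `angle_deg`
#'   applied, `crop` (x, y, w, h).
#' @export
coarse_align_and_export <- function(image, roi, pixel_ratio_um,
                                    target_shape = NULL, downsample = NULL,
                                    masks = NULL) {
  stopifnot(inherits(roi, "roi_detection"))
  rect <- roi$rotated_rect
  if (rect$width <= 0 || rect$height <= 0)
    abort("coarse_align_and_export: degenerate ROI (zero area)")
  ang <- rect$angle_deg
  rot <- affine2d(theta = -ang)
  img_r <- warp_image(image, rot, interp = "bilinear", background = 1)
  mask_r <- warp_image(matrix(as.numeric(roi$roi_mask), nrow(roi$roi_mask)),
                       rot, interp = "nearest", background = 0)
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  cen_img <- c((dims[2] + 1) / 2, (dims[1] + 1) / 2)
  # rect corners in (x, y), rotated about the image centre with the image
  th <- rect$angle_deg * pi / 180
  ux <- c(cos(th), sin(th)); uy <- c(-sin(th), cos(th))
  hw <- rect$width / 2; hh <- rect$height / 2
  corners <- rbind(rect$center + hw * ux + hh * uy,
                   rect$center + hw * ux - hh * uy,
                   rect$center - hw * ux + hh * uy,
                   rect$center - hw * ux - hh * uy)
  cr <- apply_affine(rot, corners, center = cen_img)
  x0 <- max(1L, floor(min(cr[, 1]))); x1 <- min(dims[2], ceiling(max(cr[, 1])))
  y0 <- max(1L, floor(min(cr[, 2]))); y1 <- min(dims[1], ceiling(max(cr[, 2])))
  crop_rows <- y0:y1; crop_cols <- x0:x1
  crop_shape <- c(length(crop_rows), length(crop_cols))
  if (is.null(target_shape) && is.null(downsample))
    abort("coarse_align_and_export: give either target_shape or downsample")
  if (!is.null(downsample)) {
    target_shape <- pmax(1L, round(crop_shape / downsample))
    factors <- rep(downsample, 2)
  } else {
    target_shape <- as.integer(rep_len(target_shape, 2))
    factors <- crop_shape / target_shape
  }
  crop_img <- if (is.matrix(img_r)) img_r[crop_rows, crop_cols]
              else img_r[crop_rows, crop_cols, , drop = FALSE]
  resize_one <- function(m, method) cpp_resize(m, target_shape[1], target_shape[2], method)
  out_img <- if (is.matrix(crop_img)) resize_one(crop_img, "bicubic") else {
    o <- array(0, c(target_shape, dim(crop_img)[3]))
    for (ch in seq_len(dim(crop_img)[3])) o[, , ch] <- resize_one(crop_img[, , ch], "bicubic")
    o
  }
  out_masks <- list(roi = resize_one(mask_r[crop_rows, crop_cols] * 255, "bicubic") > 128)
  for (nm in names(masks)) {
    m_r <- warp_image(matrix(as.numeric(masks[[nm]]), nrow(masks[[nm]])),
                      rot, interp = "nearest", background = 0)
    out_masks[[nm]] <- resize_one(m_r[crop_rows, crop_cols] * 255, "bicubic") > 128
  }
  structure(list(image = out_img, masks = out_masks,
                 pixel_ratio_um = pixel_ratio_um * factors,
                 downsample = factors, angle_deg = ang,
                 crop = c(x = x0, y = y0, w = crop_shape[2], h = crop_shape[1])),
            class = "working_image")
}
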