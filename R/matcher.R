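# Pluggable keypoint matching.  The default backend is a classical
# multi-scale oriented corner matcher; a deep detector-free transformer
# matcher satisfies the same contract but ships no weights here.

#' Create a keypoint matcher
#'
#' A matcher is a contract: a callable taking two grayscale images and
#' returning paired keypoint correspondences.  The `"classical"` backend
#' (default) detects multi-scale Harris corners, assigns each a dominant
#' gradient orientation, samples an oriented normalized intensity patch as
#' descriptor, and matches descriptors by mutual nearest neighbour with
#' Lowe's ratio test.  It is deterministic and needs no trained weights.  The
#' `"loftr"` backend names the detector-free transformer alternative; without
#' bundled weights it errors on use and points back to the classical
#' fallback.
#'
#' @param backend `"classical"` or `"loftr"`.
#' @param max_keypoints Per-image keypoint budget.
#' @param scales Detection scales (image is downsampled by each factor).
#' @param ratio Lowe ratio-test threshold in (0, 1].
#' @param grid,spacing Descriptor sampling grid (grid x grid samples,
#'   `spacing` px apart in the oriented frame).
#' @param on_gradient If `TRUE`, descriptors are computed on the gradient
#'   magnitude image; this makes matching robust to contrast inversion
#'   between modalities (histology vs. microCT).
#' @return An object of class `matcher`.
#' @export
matcher <- function(backend = c("classical", "loftr"), max_keypoints = 400,
                    scales = c(1, 0.5), ratio = 0.8, grid = 8, spacing = 2,
                    on_gradient = FALSE) {
  backend <- match.arg(backend)
  structure(list(backend = backend, max_keypoints = max_keypoints,
                 scales = scales, ratio = ratio, grid = grid,
                 spacing = spacing, on_gradient = on_gradient),
            class = "matcher")
}

#' @export
print.matcher <- function(x, ...) {
  cat(sprintf("<matcher> backend '%s', up to %d keypoints, scales (%s)\n",
              x$backend, x$max_keypoints, paste(x$scales, collapse = ", ")))
  invisible(x)
}

gradient_magnitude <- function(img) {
  g <- cpp_sobel(cpp_gauss_blur2d(img, 1))
  sqrt(g$gx^2 + g$gy^2)
}

# Harris corners + oriented descriptors for one image at one scale.
detect_features_scale <- function(img, scale, max_kp, grid, spacing) {
  if (scale != 1) {
    img <- cpp_resize(img, max(8L, round(nrow(img) * scale)),
                      max(8L, round(ncol(img) * scale)), "bilinear")
  }
  resp <- cpp_harris(img, sigma_d = 1, sigma_i = 2, k = 0.04)
  nr <- nrow(resp); nc <- ncol(resp)
  # 3x3 local maxima away from the border
  inner <- resp
  m <- matrix(-Inf, nr, nc)
  b <- 8L
  m[(b + 1):(nr - b), (b + 1):(nc - b)] <- inner[(b + 1):(nr - b), (b + 1):(nc - b)]
  is_max <- m > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (m >= shift_mat(m, di, dj, -Inf))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(pts = matrix(0, 0, 2), desc = matrix(0, 0, grid * grid)))
  }
  r <- resp[idx]
  ord <- order(-r)
  idx <- idx[ord, , drop = FALSE]
  # greedy spatial non-max suppression
  keep <- integer(0)
  if (nrow(idx) > max_kp * 4) idx <- idx[seq_len(max_kp * 4), , drop = FALSE]
  min_d2 <- 9
  for (t in seq_len(nrow(idx))) {
    if (length(keep) >= max_kp) break
    ok <- TRUE
    if (length(keep)) {
      d2 <- (idx[keep, 1] - idx[t, 1])^2 + (idx[keep, 2] - idx[t, 2])^2
      ok <- all(d2 >= min_d2)
    }
    if (ok) keep <- c(keep, t)
  }
  idx <- idx[keep, , drop = FALSE]
  sm <- cpp_gauss_blur2d(img, 2)
  g <- cpp_sobel(sm)
  theta <- atan2(g$gy[idx], g$gx[idx])
  pts0 <- cbind(idx[, 2] - 1, idx[, 1] - 1, theta)  # 0-based x, y for C++
  desc <- cpp_patch_descriptors(cpp_gauss_blur2d(img, 1), pts0, grid, spacing)
  list(pts = cbind(x = (idx[, 2] - 1) / scale + 1, y = (idx[, 1] - 1) / scale + 1),
       desc = desc)
}

#' Detect keypoints and descriptors in a grayscale image
#'
#' Exposed separately so that a stack of reference images (e.g. the in-silico
#' microCT slices) can be featurized once and matched against many queries.
#'
#' @param img Grayscale matrix.
#' @param m A [matcher()].
#' @return List with `pts` (n x 2, 1-based x/y) and `desc` (n x d).
#' @export
detect_features <- function(img, m = matcher()) {
  stopifnot(inherits(m, "matcher"))
  if (m$backend != "classical")
    abort(paste0("matcher backend '", m$backend, "' has no bundled weights; ",
                 "use matcher(backend = 'classical') as the fallback"))
  if (m$on_gradient) img <- gradient_magnitude(img)
  parts <- lapply(m$scales, function(s)
    detect_features_scale(img, s, ceiling(m$max_keypoints / length(m$scales)),
                          m$grid, m$spacing))
  list(pts = do.call(rbind, lapply(parts, `[[`, "pts")),
       desc = do.call(rbind, lapply(parts, `[[`, "desc")))
}

match_descriptors <- function(fa, fb, ratio) {
  na <- nrow(fa$desc); nb <- nrow(fb$desc)
  if (na == 0 || nb == 0) {
    return(list(a = matrix(0, 0, 2), b = matrix(0, 0, 2), conf = numeric(0)))
  }
  # descriptors are unit-normalized: L2^2 = 2 - 2 * cosine
  sim <- fa$desc %*% t(fb$desc)
  best_b <- max.col(sim, ties.method = "first")  # deterministic tie-breaks
  best_sim <- sim[cbind(seq_len(na), best_b)]
  second <- vapply(seq_len(na), function(i) {
    row <- sim[i, ]
    row[best_b[i]] <- -Inf
    if (nb > 1) max(row) else -Inf
  }, numeric(1))
  d1 <- sqrt(pmax(0, 2 - 2 * best_sim))
  d2 <- sqrt(pmax(0, 2 - 2 * second))
  pass_ratio <- d1 <= ratio * pmax(d2, 1e-9)
  # mutual nearest neighbour
  best_a_of_b <- max.col(t(sim), ties.method = "first")
  mutual <- best_a_of_b[best_b] == seq_len(na)
  sel <- which(pass_ratio & mutual)
  list(a = fa$pts[sel, , drop = FALSE],
       b = fb$pts[best_b[sel], , drop = FALSE],
       conf = pmax(0, pmin(1, best_sim[sel])))
}

#' Match keypoints between two grayscale images
#'
#' Returns the paired correspondences plus a parallel-displacement sanity
#' metric: the fraction of match vectors whose direction lies within 10
#' degrees of the median direction (crossing match lines indicate false
#' matches; a well-matched pair of slides yields near-parallel lines).
#'
#' @param image_a,image_b Grayscale matrices.
#' @param m A [matcher()].
#' @param features_b Optional precomputed [detect_features()] result for
#'   `image_b`.
#' @return An object of class `match_result` with fields `keypoints_a`,
#'   `keypoints_b` (n x 2 each), `n_matches`, `confidences`,
#'   `parallel_fraction`.
#' @export
match_keypoints <- function(image_a, image_b, m = matcher(), features_b = NULL) {
  fa <- detect_features(image_a, m)
  fb <- features_b %||% detect_features(image_b, m)
  mm <- match_descriptors(fa, fb, m$ratio)
  disp <- mm$b - mm$a
  nrm <- sqrt(rowSums(disp^2))
  pf <- NA_real_
  if (length(nrm)) {
    moving <- nrm > 0.5
    if (any(moving)) {
      ang <- atan2(disp[moving, 2], disp[moving, 1])
      med <- atan2(median(sin(ang)), median(cos(ang)))
      dd <- abs(((ang - med + pi) %% (2 * pi)) - pi)
      pf <- (sum(dd <= 10 * pi / 180) + sum(!moving)) / length(nrm)
    } else pf <- 1
  }
  structure(list(keypoints_a = mm$a, keypoints_b = mm$b,
                 n_matches = nrow(mm$a), confidences = mm$conf,
                 parallel_fraction = pf),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matches, parallel fraction %.2f\n",
              x$n_matches, x$parallel_fraction))
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) {
  if (x$n_matches == 0) {
    return(tibble(xa = numeric(), ya = numeric(), xb = numeric(),
                  yb = numeric(), confidence = numeric()))
  }
  tibble(xa = x$keypoints_a[, 1], ya = x$keypoints_a[, 2],
         xb = x$keypoints_b[, 1], yb = x$keypoints_b[, 2],
         confidence = x$confidences)
}

# Robust similarity transform (about the image centre) from matched
# keypoints: a 2-point RANSAC (two pairs determine a similarity exactly)
# scores consensus sets, and the largest set gets a least-squares refit.
# Returns an affine2d mapping a-coordinates into b-coordinates, or NULL when
# under-determined.  Deterministic: candidate pairs are enumerated, not drawn.
estimate_similarity <- function(kp_a, kp_b, center, inlier_tol = 3,
                                max_candidates = 256) {
  n <- nrow(kp_a)
  if (n < 3) return(NULL)
  fit_ls <- function(A, B) {
    mu_a <- colMeans(A); mu_b <- colMeans(B)
    Ac <- sweep(A, 2, mu_a); Bc <- sweep(B, 2, mu_b)
    S <- t(Ac) %*% Bc / nrow(A)
    sv <- svd(S)
    dsgn <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, dsgn))
    R <- sv$v %*% D %*% t(sv$u)
    s <- sum(diag(D) * sv$d) / mean(rowSums(Ac^2))
    list(R = R, s = s, t = mu_b - s * as.numeric(R %*% mu_a))
  }
  residuals <- function(f) {
    pred <- sweep(kp_a %*% t(f$R) * f$s, 2, f$t, FUN = "+")
    sqrt(rowSums((pred - kp_b)^2))
  }
  # enumerate well-separated index pairs, capped for large match sets
  pairs <- utils::combn(min(n, 24), 2)
  if (ncol(pairs) > max_candidates) pairs <- pairs[, seq_len(max_candidates)]
  best_inliers <- NULL
  for (cnd in seq_len(ncol(pairs))) {
    i <- pairs[1, cnd]; j <- pairs[2, cnd]
    va <- kp_a[j, ] - kp_a[i, ]; vb <- kp_b[j, ] - kp_b[i, ]
    la <- sqrt(sum(va^2)); lb <- sqrt(sum(vb^2))
    if (la < 4 || lb < 1e-6) next
    s <- lb / la
    if (s < 0.5 || s > 2) next
    th <- atan2(vb[2], vb[1]) - atan2(va[2], va[1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t_vec <- kp_b[i, ] - s * as.numeric(R %*% kp_a[i, ])
    inl <- residuals(list(R = R, s = s, t = t_vec)) <= inlier_tol
    if (sum(inl) > sum(best_inliers %||% 0)) best_inliers <- inl
  }
  if (is.null(best_inliers) || sum(best_inliers) < 3) {
    f <- fit_ls(kp_a, kp_b)  # no consensus: fall back to plain least squares
  } else {
    f <- fit_ls(kp_a[best_inliers, , drop = FALSE], kp_b[best_inliers, , drop = FALSE])
    # re-collect inliers, then tighten adaptively: near-miss matches a pixel
    # or two off (keypoint quantization) otherwise drag the fit off-centre
    for (tol in c(inlier_tol, max(0.5, 2 * median(residuals(f))))) {
      inl <- residuals(f) <= tol
      if (sum(inl) >= 4)
        f <- fit_ls(kp_a[inl, , drop = FALSE], kp_b[inl, , drop = FALSE])
    }
  }
  theta <- atan2(f$R[2, 1], f$R[1, 1]) * 180 / pi
  # convert q = sR p + T into q = c + sR (p - c) + t
  t_param <- f$t - center + f$s * as.numeric(f$R %*% center)
  if (f$s <= 0 || !all(is.finite(c(t_param, theta, f$s)))) return(NULL)
  affine2d(tx = t_param[1], ty = t_param[2], theta = theta, s = f$s)
}
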