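# Stack pre-alignment: the sequential cross-entropy affine optimizer and
# stepwise affine propagation with keypoint-count-based reference selection.

image_center <- function(img) {
  d <- if (is.matrix(img)) dim(img) else dim(img)[1:2]
  c((d[2] + 1) / 2, (d[1] + 1) / 2)
}

normalize01 <- function(img) {
  r <- range(img, finite = TRUE)
  if (diff(r) < 1e-12) return(img * 0)
  (img - r[1]) / (r[2] - r[1])
}

#' Cross-entropy dissimilarity between a fixed image and a warped moving image
#'
#' Both images are normalized to `[0, 1]` and clamped to `[eps, 1 - eps]`;
#' the objective is the mean Bernoulli cross-entropy
#' `-mean(f * log(m) + (1 - f) * log(1 - m))` over the warped overlap (pixels
#' the moving image actually maps onto).  Configurations whose overlap falls
#' below `min_overlap` of the frame are assigned `Inf` so the optimizer
#' cannot escape by shrinking the common support.
#'
#' @param moving,fixed Grayscale matrices of identical shape.
#' @param a An [affine2d()] applied to `moving`.
#' @param eps Clamping constant.
#' @param min_overlap Minimum admissible overlap fraction.
#' @return Scalar objective (lower is better).
#' @export
cross_entropy_objective <- function(moving, fixed, a, eps = 1e-6, min_overlap = 0.25) {
  warped <- cpp_warp_affine(moving, a$tx, a$ty, a$theta, a$s, "bilinear", -1)
  ok <- warped >= 0
  if (!any(ok)) abort("cross_entropy_objective: empty overlap after warp")
  if (mean(ok) < min_overlap) return(Inf)
  f <- pmin(pmax(fixed[ok], eps), 1 - eps)
  m <- pmin(pmax(warped[ok], eps), 1 - eps)
  val <- -mean(f * log(m) + (1 - f) * log(1 - m))
  if (!is.finite(val)) abort("cross_entropy_objective: non-finite objective")
  val
}

#' Sequential cross-entropy affine optimizer
#'
#' Coordinate descent over the decomposed transform: first the optimal
#' translation (coarse exhaustive grid, stride 4 px — half the default
#' phantom's correlation length, so the basin cannot fall between grid
#' points — swept over a handful of
#' candidate rotations so a rotation mismatch cannot lock the translation
#' onto a false optimum, then 1-D golden-section refinement of each
#' component), then the rotation, then the isotropic scale, each a bracketed
#' 1-D search within its bounds.  Splitting the transform this way stabilises
#' the search and avoids false joint optima.
#' The objective is [cross_entropy_objective()]; the returned objective never
#' exceeds the objective at `init`, and each stage is non-increasing.
#'
#' @param moving,fixed Grayscale matrices of identical shape; intensities are
#'   normalized internally.
#' @param init An [affine2d()] starting point.
#' @param bounds List with `translate` (max |shift| in px around init),
#'   `rotate` (max |angle| in degrees around init), `scale` (absolute range).
#' @param tol List of stage tolerances: `translate` px, `rotate` degrees,
#'   `scale` (absolute).
#' @return The optimized [affine2d()]; attribute `"trace"` records the
#'   objective after each stage (init, translation, rotation, scale).
#' @export
optimize_affine <- function(moving, fixed, init = affine2d(),
                            bounds = list(translate = 32, rotate = 15,
                                          scale = c(0.9, 1.1)),
                            tol = list(translate = 0.25, rotate = 0.05,
                                       scale = 0.001)) {
  stopifnot(is.matrix(moving), is.matrix(fixed), all(dim(moving) == dim(fixed)))
  moving <- normalize01(moving); fixed <- normalize01(fixed)
  obj <- function(tx, ty, th, s)
    cross_entropy_objective(moving, fixed, affine2d(tx, ty, th, s))
  cur <- init
  f_init <- obj(cur$tx, cur$ty, cur$theta, cur$s)
  trace <- c(init = f_init)
  best_f <- f_init  # may be Inf (overlap floor); the coarse scan can recover
  # --- translation: coarse grid (swept over a few candidate rotations, which
  # keeps the stage from locking onto the false translation optimum a rotation
  # mismatch induces) then per-component golden-section refinement
  gr <- seq(-bounds$translate, bounds$translate, by = 4)
  th_cand <- unique(c(cur$theta, seq(init$theta - bounds$rotate,
                                     init$theta + bounds$rotate, by = 2.5)))
  for (th in th_cand) {
    grid_vals <- outer(gr, gr, Vectorize(function(dx, dy)
      obj(init$tx + dx, init$ty + dy, th, cur$s)))
    if (min(grid_vals) < best_f) {
      k <- arrayInd(which.min(grid_vals), dim(grid_vals))
      cur$tx <- init$tx + gr[k[1]]
      cur$ty <- init$ty + gr[k[2]]
      cur$theta <- th  # provisional; properly optimized in the rotation stage
      best_f <- min(grid_vals)
    }
  }
  if (!is.finite(best_f))
    abort("optimize_affine: no admissible overlap found within the translation bounds")
  for (pass in 1:2) {
    o <- optimize(function(t) obj(t, cur$ty, cur$theta, cur$s),
                  interval = c(cur$tx - 8, cur$tx + 8), tol = tol$translate)
    if (o$objective < best_f) { cur$tx <- o$minimum; best_f <- o$objective }
    o <- optimize(function(t) obj(cur$tx, t, cur$theta, cur$s),
                  interval = c(cur$ty - 8, cur$ty + 8), tol = tol$translate)
    if (o$objective < best_f) { cur$ty <- o$minimum; best_f <- o$objective }
  }
  trace <- c(trace, translation = best_f)
  # --- rotation: coarse 1-degree sweep then refinement
  ths <- seq(init$theta - bounds$rotate, init$theta + bounds$rotate, by = 1)
  fv <- vapply(ths, function(t) obj(cur$tx, cur$ty, t, cur$s), numeric(1))
  if (min(fv) < best_f) { cur$theta <- ths[which.min(fv)]; best_f <- min(fv) }
  o <- optimize(function(t) obj(cur$tx, cur$ty, t, cur$s),
                interval = c(cur$theta - 1, cur$theta + 1), tol = tol$rotate)
  if (o$objective < best_f) { cur$theta <- o$minimum; best_f <- o$objective }
  trace <- c(trace, rotation = best_f)
  # --- scale
  ss <- seq(bounds$scale[1], bounds$scale[2], by = 0.01)
  fv <- vapply(ss, function(t) obj(cur$tx, cur$ty, cur$theta, t), numeric(1))
  if (min(fv) < best_f) { cur$s <- ss[which.min(fv)]; best_f <- min(fv) }
  o <- optimize(function(t) obj(cur$tx, cur$ty, cur$theta, t),
                interval = pmax(c(cur$s - 0.01, cur$s + 0.01), 1e-3),
                tol = tol$scale)
  if (o$objective < best_f) { cur$s <- o$minimum; best_f <- o$objective }
  trace <- c(trace, scale = best_f)
  # second sweep: small-bracket refinement of each component in turn, which
  # resolves the residual coupling between translation, rotation and scale
  for (pass in 1:2) {
    o <- optimize(function(t) obj(t, cur$ty, cur$theta, cur$s),
                  interval = c(cur$tx - 4, cur$tx + 4), tol = tol$translate)
    if (o$objective < best_f) { cur$tx <- o$minimum; best_f <- o$objective }
    o <- optimize(function(t) obj(cur$tx, t, cur$theta, cur$s),
                  interval = c(cur$ty - 4, cur$ty + 4), tol = tol$translate)
    if (o$objective < best_f) { cur$ty <- o$minimum; best_f <- o$objective }
    o <- optimize(function(t) obj(cur$tx, cur$ty, t, cur$s),
                  interval = c(cur$theta - 1, cur$theta + 1), tol = tol$rotate)
    if (o$objective < best_f) { cur$theta <- o$minimum; best_f <- o$objective }
    o <- optimize(function(t) obj(cur$tx, cur$ty, cur$theta, t),
                  interval = pmax(c(cur$s - 0.01, cur$s + 0.01), 1e-3),
                  tol = tol$scale)
    if (o$objective < best_f) { cur$s <- o$minimum; best_f <- o$objective }
  }
  trace <- c(trace, refine = best_f)
  out <- affine2d(cur$tx, cur$ty, cur$theta, cur$s)
  attr(out, "trace") <- trace
  out
}

#' Pre-align a serial-section stack by stepwise affine propagation
#'
#' Starting from one end of the stack, each slide is registered to a
#' reference chosen among its already-aligned predecessors within a window:
#' the candidate with the highest matched-keypoint count wins.  The
#' registration is initialised from a least-squares similarity fit to the
#' matches and refined with [optimize_affine()].  Because each slide is
#' aligned against an already-aligned reference, its estimated transform is
#' directly the cumulative transform into the common frame.  A slide with no
#' matches to any candidate is flagged and passed through with the identity
#' transform rather than dropped.
#'
#' @param slides List of grayscale matrices (or a `histology_stack`, whose
#'   slides are converted to grayscale).
#' @param m A [matcher()].
#' @param direction `"forward"` (first slide anchors the frame) or
#'   `"backward"`.
#' @param window Number of preceding slides considered as references.
#' @param refine If `TRUE` (default) refine the keypoint initialisation with
#'   the cross-entropy optimizer.
#' @param refine_bounds Bounds passed to [optimize_affine()] around the
#'   keypoint initialisation.
#' @return List of class `prealignment`: `aligned` (list of warped slides),
#'   `transforms` (tibble: slide, tx, ty, theta, s, n_matches, reference,
#'   flagged), `direction`.
#' @export
prealign_stack <- function(slides, m = matcher(), direction = c("forward", "backward"),
                           window = 5, refine = TRUE,
                           refine_bounds = list(translate = 8, rotate = 3,
                                                scale = c(0.95, 1.05))) {
  direction <- match.arg(direction)
  if (inherits(slides, "histology_stack")) slides <- lapply(slides$slides, rgb_to_gray)
  slides <- lapply(slides, function(s) if (is.matrix(s)) s else rgb_to_gray(s))
  n <- length(slides)
  if (n < 2) abort("prealign_stack: need at least 2 slides")
  ord <- if (direction == "forward") seq_len(n) else rev(seq_len(n))
  aligned <- vector("list", n)
  feats <- vector("list", n)
  rows <- vector("list", n)
  first <- ord[1]
  aligned[[first]] <- slides[[first]]
  feats[[first]] <- detect_features(aligned[[first]], m)
  rows[[first]] <- tibble(slide = first, tx = 0, ty = 0, theta = 0, s = 1,
                          n_matches = NA_integer_, reference = NA_integer_,
                          flagged = FALSE)
  for (t in 2:n) {
    i <- ord[t]
    cand <- ord[seq(max(1, t - window), t - 1)]
    best <- NULL; best_ref <- NA_integer_
    for (j in cand) {
      mr <- match_keypoints(slides[[i]], aligned[[j]], m, features_b = feats[[j]])
      if (is.null(best) || mr$n_matches > best$n_matches) { best <- mr; best_ref <- j }
    }
    a <- NULL
    flagged <- FALSE
    if (!is.null(best) && best$n_matches >= 3) {
      a <- estimate_similarity(best$keypoints_a, best$keypoints_b,
                               center = image_center(slides[[i]]))
    }
    if (is.null(a)) {
      if (is.null(best) || best$n_matches == 0) {
        warn(sprintf("prealign_stack: slide %d has no matches to any candidate reference; passing through with identity", i))
        flagged <- TRUE
      }
      a <- affine2d()
    }
    if (refine && !flagged) {
      a <- tryCatch({
        r <- optimize_affine(slides[[i]], aligned[[best_ref]], init = a,
                             bounds = refine_bounds)
        attr(r, "trace") <- NULL
        r
      }, error = function(e) a)  # keep the keypoint initialisation
    }
    aligned[[i]] <- warp_image(slides[[i]], a, background = 0)
    feats[[i]] <- detect_features(aligned[[i]], m)
    rows[[i]] <- tibble(slide = i, tx = a$tx, ty = a$ty, theta = a$theta, s = a$s,
                        n_matches = if (is.null(best)) 0L else as.integer(best$n_matches),
                        reference = best_ref, flagged = flagged)
  }
  structure(list(aligned = aligned,
                 transforms = dplyr::bind_rows(rows[order(seq_len(n))]),
                 direction = direction),
            class = "prealignment")
}

#' @export
print.prealignment <- function(x, ...) {
  cat(sprintf("<prealignment> %d slides (%s), %d flagged\n",
              length(x$aligned), x$direction, sum(x$transforms$flagged)))
  invisible(x)
}
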