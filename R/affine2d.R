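#' In-plane affine transform (translation, rotation, isotropic scale)
#'
#' The decomposed 2D affine transform used throughout the alignment stages.
#' Its matrix form is `T(tx, ty) %*% R(theta) %*% S(s)` acting about the image
#' centre: a point `p` (in x = column, y = row pixel coordinates) maps to
#' `center + s * R(theta) (p - center) + t`.  Keeping the decomposition
#' explicit (rather than a free 6-parameter matrix) mirrors the sequential
#' translation -> rotation -> scale optimisation of the registration stage.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in degrees, counter-clockwise in (x right, y down)
#'   pixel coordinates.
#' @param s Isotropic scale factor, must be positive.
#' @return An object of class `affine2d`.
#' @examples
#' a <- affine2d(3, -2, theta = 10, s = 1.02)
#' compose_affine(a, invert_affine(a)) # identity up to rounding
#' @export
affine2d <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  stopifnot(is.numeric(tx), is.numeric(ty), is.numeric(theta), is.numeric(s))
  if (!is.finite(s) || s <= 0) abort("affine2d: scale `s` must be positive and finite")
  if (!all(is.finite(c(tx, ty, theta)))) abort("affine2d: parameters must be finite")
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 theta = as.numeric(theta), s = as.numeric(s)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> tx=%.3f ty=%.3f theta=%.3f deg s=%.4f\n",
              x$tx, x$ty, x$theta, x$s))
  invisible(x)
}

#' @export
format.affine2d <- function(x, ...) {
  sprintf("[%.4f, %.4f, %.4f, %.4f]", x$tx, x$ty, x$theta, x$s)
}

is_affine2d <- function(x) inherits(x, "affine2d")

#' Linear part of an affine2d as a 2x2 matrix
#' @param a An [affine2d()].
#' @return A 2x2 numeric matrix `s * R(theta)`.
#' @export
affine_linear <- function(a) {
  th <- a$theta * pi / 180
  a$s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply an affine2d to points
#'
#' @param a An [affine2d()].
#' @param pts A two-column matrix of (x, y) coordinates.
#' @param center The fixed point of rotation/scaling, default `c(0, 0)`.
#' @return Transformed coordinate matrix of the same shape.
#' @export
apply_affine <- function(a, pts, center = c(0, 0)) {
  stopifnot(is_affine2d(a))
  pts <- matrix(as.numeric(pts), ncol = 2)
  M <- affine_linear(a)
  swept <- sweep(pts, 2, center)
  out <- t(M %*% t(swept))
  sweep(out, 2, center + c(a$tx, a$ty), FUN = "+")
}

#' Compose two affine2d transforms
#'
#' `apply_affine(compose_affine(a, b), p)` equals
#' `apply_affine(a, apply_affine(b, p))` about a shared centre.
#'
#' @param a,b [affine2d()] objects; `b` is applied first.
#' @return The composed [affine2d()].
#' @export
compose_affine <- function(a, b) {
  stopifnot(is_affine2d(a), is_affine2d(b))
  M <- affine_linear(a)
  tb <- as.numeric(M %*% c(b$tx, b$ty))
  affine2d(tx = a$tx + tb[1], ty = a$ty + tb[2],
           theta = a$theta + b$theta, s = a$s * b$s)
}

#' Invert an affine2d transform
#' @param a An [affine2d()].
#' @return The inverse [affine2d()].
#' @export
invert_affine <- function(a) {
  stopifnot(is_affine2d(a))
  th <- -a$theta * pi / 180
  s <- 1 / a$s
  M <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_inv <- -as.numeric(M %*% c(a$tx, a$ty))
  affine2d(tx = t_inv[1], ty = t_inv[2], theta = -a$theta, s = s)
}

#' Warp a 2D image (or each channel of an RGB array) by an affine2d
#'
#' The transform acts about the image centre.  Intensity images are resampled
#' bilinearly, label masks with nearest-neighbour interpolation.
#'
#' @param img A numeric matrix, or an H x W x 3 array.
#' @param a An [affine2d()].
#' @param interp `"bilinear"` or `"nearest"`.
#' @param background Fill value for pixels mapped from outside the image.
#' @return Warped image of the same shape.
#' @export
warp_image <- function(img, a, interp = c("bilinear", "nearest"), background = 0) {
  stopifnot(is_affine2d(a))
  interp <- match.arg(interp)
  if (is.matrix(img)) {
    return(cpp_warp_affine(img, a$tx, a$ty, a$theta, a$s, interp, background))
  }
  if (length(dim(img)) == 3) {
    out <- img
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- cpp_warp_affine(img[, , ch], a$tx, a$ty, a$theta, a$s, interp, background)
    return(out)
  }
  abort("warp_image: `img` must be a matrix or an H x W x C array")
}

#' @export
tidy.affine2d <- function(x, ...) {
  tibble(tx = x$tx, ty = x$ty, theta = x$theta, s = x$s)
}

affine_from_row <- function(row) {
  affine2d(tx = row$tx, ty = row$ty, theta = row$theta, s = row$s)
}

#' Warp an image into a (possibly differently sized) target frame
#'
#' The transform maps moving-image coordinates into target-frame coordinates
#' about the moving image's centre: useful when a slide scanned on a larger
#' canvas is resampled onto the CT slice grid.
#'
#' @param img Numeric matrix (moving image).
#' @param a An [affine2d()] fitted from moving to target coordinates.
#' @param out_shape Target (rows, cols).
#' @param interp `"bilinear"` or `"nearest"`.
#' @param background Fill for unmapped target pixels.
#' @return A matrix of dimension `out_shape`.
#' @export
warp_to_frame <- function(img, a, out_shape, interp = c("bilinear", "nearest"),
                          background = 0) {
  stopifnot(is_affine2d(a), is.matrix(img))
  interp <- match.arg(interp)
  cpp_warp_affine_frame(img, out_shape[1], out_shape[2], a$tx, a$ty, a$theta,
                        a$s, interp, background)
}

# serialization convention: [tx, ty, theta_deg, scale]
affine_to_vec <- function(a) c(a$tx, a$ty, a$theta, a$s)
affine_from_vec <- function(v) affine2d(v[1], v[2], v[3], v[4])
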