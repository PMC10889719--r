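# Open 3D trabecular micromorphometry on binary volumes: voxel-count volumes,
# coarea surface estimation, maximal-sphere thickness/separation,
# dilation-difference pattern factor and structure model index,
# mean-intercept-length anisotropy, box-counting fractal dimension, and
# component/Euler topology.

#' Otsu's threshold
#' @param x Numeric vector or array.
#' @param nbins Histogram bins.
#' @return Scalar threshold maximizing between-class variance.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  r <- range(v, finite = TRUE)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(floor((v - r[1]) / diff(r) * nbins) + 1, nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  r[1] + (k / nbins) * diff(r)
}

#' Binarize a labelled volume or grayscale CT volume
#'
#' @param x A [labeled_volume()], [binary_volume()] or 3D numeric array.
#' @param rule One of `"labels:bone"`, `"labels:bone,graft"` (default for
#'   labelled input; both classes are radiopaque so the CT foreground
#'   necessarily includes graft), `"otsu"` (default for grayscale), or
#'   `"fixed:<t>"` for a manual threshold.
#' @param spacing_um Voxel spacing for plain-array input.
#' @return A [binary_volume()].
#' @export
binarize_volume <- function(x, rule = NULL, spacing_um = 1) {
  if (inherits(x, "binary_volume")) return(x)
  if (inherits(x, "labeled_volume")) {
    rule <- rule %||% "labels:bone,graft"
    if (!startsWith(rule, "labels:"))
      abort("binarize_volume: labelled input needs a labels: rule")
    classes <- strsplit(sub("^labels:", "", rule), ",")[[1]]
    codes <- c(bone = 1L, graft = 2L)[classes]
    if (anyNA(codes)) abort("binarize_volume: unknown class in rule")
    fg <- array(x$voxels %in% codes, dim(x$voxels))
    if (!any(fg)) warn("binarize_volume: empty foreground")
    return(binary_volume(fg, x$spacing_um))
  }
  rule <- rule %||% "otsu"
  thr <- if (rule == "otsu") otsu_threshold(x)
         else if (startsWith(rule, "fixed:")) as.numeric(sub("^fixed:", "", rule))
         else abort("binarize_volume: unknown rule")
  fg <- array(x > thr, dim(x))
  if (!any(fg)) warn("binarize_volume: empty foreground")
  binary_volume(fg, spacing_um)
}

shift3 <- function(a, d1, d2, d3, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  s1 <- max(1, 1 + d1):min(dm[1], dm[1] + d1)
  s2 <- max(1, 1 + d2):min(dm[2], dm[2] + d2)
  s3 <- max(1, 1 + d3):min(dm[3], dm[3] + d3)
  out[s1, s2, s3] <- a[s1 - d1, s2 - d2, s3 - d3]
  out
}

dilate3_cross <- function(fg) {
  fg | shift3(fg, 1, 0, 0) | shift3(fg, -1, 0, 0) |
    shift3(fg, 0, 1, 0) | shift3(fg, 0, -1, 0) |
    shift3(fg, 0, 0, 1) | shift3(fg, 0, 0, -1)
}

# Maximal-sphere local thickness under a mirror (stationarity) assumption at
# the analysis border: the phase is reflected `pad` voxels outward before the
# distance transform, so structures cut by the field of view are neither
# clipped nor credited with spurious depth.  Spheres larger than the mirror
# horizon are reported at the horizon.
local_thickness_map <- function(fg, pad = 16L) {
  d <- dim(fg)
  pad <- as.integer(pad)
  idx <- lapply(1:3, function(a) {
    m <- min(pad, d[a])
    c(rev(seq_len(m)), seq_len(d[a]), d[a] + 1 - seq_len(m))
  })
  p <- fg[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  e <- cpp_edt3d_sq(p)
  th <- cpp_local_thickness(p, e, rmax = pad)
  # regions wider than the mirror horizon saturate at 2*pad - 1: every voxel
  # within `pad` of a saturated centre belongs to one of its (capped) spheres
  far <- array(e >= pad^2, dim(p))
  if (any(far)) {
    d2 <- cpp_edt3d_sq(!far)
    sat <- p & (d2 <= pad^2)
    th[sat] <- pmax(th[sat], 2 * pad - 1)
  }
  m <- vapply(1:3, function(a) min(pad, d[a]), integer(1))
  array(th, dim(p))[m[1] + seq_len(d[1]), m[2] + seq_len(d[2]), m[3] + seq_len(d[3])]
}

# surface area (voxel^2 units) by the coarea formula on a smoothed indicator
surface_area_vox <- function(fg, sigma = 1) {
  u <- cpp_blur3d(array(as.numeric(fg), dim(fg)), sigma)
  d <- dim(u)
  gx <- (u[c(2:d[1], d[1]), , , drop = FALSE] - u[c(1, 1:(d[1] - 1)), , , drop = FALSE]) / 2
  gy <- (u[, c(2:d[2], d[2]), , drop = FALSE] - u[, c(1, 1:(d[2] - 1)), , drop = FALSE]) / 2
  gz <- (u[, , c(2:d[3], d[3]), drop = FALSE] - u[, , c(1, 1:(d[3] - 1)), drop = FALSE]) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2))
}

# Euler characteristic of the union of closed unit voxels:
# chi = V - E + F - C over the cubical complex.
euler_characteristic <- function(fg) {
  count_cells <- function(shift_axes) {
    dm <- dim(fg)
    outd <- dm + as.integer(1:3 %in% shift_axes)
    A <- array(FALSE, outd)
    offs <- expand.grid(lapply(1:3, function(a) if (a %in% shift_axes) 0:1 else 0))
    for (r in seq_len(nrow(offs))) {
      o <- as.integer(offs[r, ])
      A[o[1] + seq_len(dm[1]), o[2] + seq_len(dm[2]), o[3] + seq_len(dm[3])] <-
        A[o[1] + seq_len(dm[1]), o[2] + seq_len(dm[2]), o[3] + seq_len(dm[3])] | fg
    }
    sum(A)
  }
  V <- count_cells(1:3)
  E <- count_cells(c(2, 3)) + count_cells(c(1, 3)) + count_cells(c(1, 2))
  Fc <- count_cells(1) + count_cells(2) + count_cells(3)
  C <- sum(fg)
  V - E + Fc - C
}

fibonacci_directions <- function(n = 49) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)          # polar angle over the upper hemisphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Mean-intercept-length tensor via directional boundary-crossing densities.
mil_tensor <- function(fg, n_dir = 49) {
  u <- cpp_blur3d(array(as.numeric(fg), dim(fg)), 1)
  d <- dim(u)
  g1 <- (u[c(2:d[1], d[1]), , , drop = FALSE] - u[c(1, 1:(d[1] - 1)), , , drop = FALSE]) / 2
  g2 <- (u[, c(2:d[2], d[2]), , drop = FALSE] - u[, c(1, 1:(d[2] - 1)), , drop = FALSE]) / 2
  g3 <- (u[, , c(2:d[3], d[3]), drop = FALSE] - u[, , c(1, 1:(d[3] - 1)), drop = FALSE]) / 2
  dirs <- fibonacci_directions(n_dir)
  bv <- sum(fg)
  cross_dens <- vapply(seq_len(nrow(dirs)), function(i) {
    sum(abs(g1 * dirs[i, 1] + g2 * dirs[i, 2] + g3 * dirs[i, 3])) / 2
  }, numeric(1))
  mil <- 2 * bv / pmax(cross_dens, 1e-9)
  # fit the quadratic form  w' A w = 1 / MIL(w)^2
  W <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  y <- 1 / mil^2
  cf <- solve(crossprod(W), crossprod(W, y))
  A <- matrix(c(cf[1], cf[4], cf[5],
                cf[4], cf[2], cf[6],
                cf[5], cf[6], cf[3]), 3, 3)
  ev <- eigen(A, symmetric = TRUE)$values
  ev <- pmax(ev, max(ev) * 1e-6)
  # MIL eigenvalues scale as 1/sqrt(ev); DA = longest / shortest principal MIL
  list(DA = sqrt(max(ev) / min(ev)), eigenvalues = ev)
}

fractal_dimension <- function(fg) {
  bg6 <- !fg
  boundary <- fg & (shift3(bg6, 1, 0, 0, TRUE) | shift3(bg6, -1, 0, 0, TRUE) |
                    shift3(bg6, 0, 1, 0, TRUE) | shift3(bg6, 0, -1, 0, TRUE) |
                    shift3(bg6, 0, 0, 1, TRUE) | shift3(bg6, 0, 0, -1, TRUE))
  if (!any(boundary)) return(NA_real_)
  idx <- which(boundary, arr.ind = TRUE)
  sizes <- 2^(1:5)
  sizes <- sizes[sizes <= min(dim(fg)) / 2]
  if (length(sizes) < 2) return(NA_real_)
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind((idx[, 1] - 1) %/% s, (idx[, 2] - 1) %/% s, (idx[, 3] - 1) %/% s)))
  }, numeric(1))
  -coef(lm(log(counts) ~ log(sizes)))[[2]]
}

resample_isotropic <- function(bv) {
  sp <- bv$spacing_um
  if (diff(range(sp)) < 1e-9) return(bv)
  h <- max(sp)
  d <- dim(bv$voxels)
  nd <- pmax(1L, round(d * sp / h))
  idx <- lapply(1:3, function(a) pmin(d[a], pmax(1L, round((seq_len(nd[a]) - 0.5) * h / sp[a] + 0.5))))
  binary_volume(bv$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], h)
}

#' Compute the 3D micromorphometric parameter set of a binary volume
#'
#' Voxel counting gives TV, BV, BV/TV and total porosity; a triangulation-free
#' coarea estimate on the smoothed indicator gives bone surface BS (and TS,
#' the surface of the analysed box); trabecular thickness Tb.Th and
#' separation Tb.Sp use the local maximal-sphere method on the distance
#' transform of the phase and its complement (the same code path, so the
#' complement duality is exact); Tb.N = (BV/TV) / Tb.Th; Tb.Pf and SMI come
#' from the surface/volume differences under a one-voxel dilation; DA is the
#' ratio of extreme mean-intercept-length eigenvalues; FD is a 3D
#' box-counting dimension of the boundary; Obj.N, Po.N(cl) and EuN count
#' 26-connected foreground objects, enclosed 6-connected background pores and
#' the Euler characteristic of the voxel complex.  Anisotropic input is
#' resampled to isotropic voxels at the coarsest axis spacing
#' (nearest-neighbour) first.
#'
#' @param bv A [binary_volume()] (or anything [binarize_volume()] accepts).
#' @param rule Binarization rule when `bv` is not already binary.
#' @param surface_sigma Smoothing (voxels) for the coarea surface estimate.
#' @param n_dir Number of mean-intercept-length directions.
#' @return A one-row tibble with columns `TV`, `BV`, `BV/TV`, `TS`, `BS`,
#'   `BS/BV`, `BS/TV`, `Tb.Th`, `Tb.Sp`, `Tb.N`, `Tb.Pf`, `SMI`, `DA`, `FD`,
#'   `Obj.N`, `Po.N(cl)`, `Po`, `EuN`, centroid (`Ct.X/Y/Z`) and second
#'   moments.  Units: µm for lengths, µm² and µm³ for surfaces and volumes,
#'   percent for BV/TV and Po.  Degenerate (all-foreground or all-background)
#'   input yields the defined degenerate values with `NA` thickness, never an
#'   error.
#' @export
compute_morphometry <- function(bv, rule = NULL, surface_sigma = 1, n_dir = 49) {
  if (!inherits(bv, "binary_volume")) bv <- binarize_volume(bv, rule)
  bv <- resample_isotropic(bv)
  h <- bv$spacing_um[1]
  fg <- bv$voxels
  d <- dim(fg)
  n_tot <- prod(d)
  n_fg <- sum(fg)
  TV <- n_tot * h^3
  BV <- n_fg * h^3
  bvtv <- 100 * n_fg / n_tot
  TS <- 2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3]) * h^2
  base <- tibble(`TV` = TV, `BV` = BV, `BV/TV` = bvtv, `TS` = TS,
                 `BS` = 0, `BS/BV` = NA_real_, `BS/TV` = 0,
                 `Tb.Th` = NA_real_, `Tb.Sp` = NA_real_, `Tb.N` = NA_real_,
                 `Tb.Pf` = NA_real_, `SMI` = NA_real_, `DA` = NA_real_,
                 `FD` = NA_real_, `Obj.N` = 0L, `Po.N(cl)` = 0L,
                 `Po` = 100 - bvtv, `EuN` = 0L,
                 `Ct.X` = NA_real_, `Ct.Y` = NA_real_, `Ct.Z` = NA_real_,
                 `Ixx` = NA_real_, `Iyy` = NA_real_, `Izz` = NA_real_)
  if (n_fg == 0) return(base)
  if (n_fg == n_tot) {
    base$`Obj.N` <- 1L; base$`EuN` <- 1L
    idx <- which(fg, arr.ind = TRUE)
    base[c("Ct.X", "Ct.Y", "Ct.Z")] <- as.list(colMeans(idx)[c(2, 1, 3)] * h)
    return(base)
  }
  S_vox <- surface_area_vox(fg, surface_sigma)
  BS <- S_vox * h^2
  # thickness / separation: identical code path on phase and complement
  th_fg <- local_thickness_map(fg)
  tbth <- mean(th_fg[fg]) * h
  bg <- !fg
  th_bg <- local_thickness_map(bg)
  tbsp <- mean(th_bg[bg]) * h
  tbn <- (n_fg / n_tot) / tbth
  # dilation differences
  fg_d <- dilate3_cross(fg)
  S2 <- surface_area_vox(fg_d, surface_sigma) * h^2
  V2 <- sum(fg_d) * h^3
  tbpf <- if (V2 > BV) (BS - S2) / (V2 - BV) else NA_real_
  Sprime <- (S2 - BS) / h
  smi <- 6 * (Sprime * BV / BS^2)
  mil <- mil_tensor(fg, n_dir)
  fd <- fractal_dimension(fg)
  objn <- max(cpp_label3d(fg, 26L))
  lab_bg <- cpp_label3d(bg, 6L)
  border_labs <- unique(c(lab_bg[1, , ], lab_bg[d[1], , ], lab_bg[, 1, ],
                          lab_bg[, d[2], ], lab_bg[, , 1], lab_bg[, , d[3]]))
  poncl <- length(setdiff(unique(as.integer(lab_bg[lab_bg > 0])), border_labs))
  eun <- euler_characteristic(fg)
  idx <- which(fg, arr.ind = TRUE)
  cen <- colMeans(idx) * h   # (row=y, col=x, plane=z)
  rel <- sweep(idx * h, 2, cen)
  base$`BS` <- BS
  base$`BS/BV` <- BS / BV
  base$`BS/TV` <- BS / TV
  base$`Tb.Th` <- tbth
  base$`Tb.Sp` <- tbsp
  base$`Tb.N` <- tbn
  base$`Tb.Pf` <- tbpf
  base$`SMI` <- smi
  base$`DA` <- mil$DA
  base$`FD` <- fd
  base$`Obj.N` <- as.integer(objn)
  base$`Po.N(cl)` <- as.integer(poncl)
  base$`EuN` <- as.integer(eun)
  base$`Ct.X` <- cen[2]; base$`Ct.Y` <- cen[1]; base$`Ct.Z` <- cen[3]
  base$`Ixx` <- sum(rel[, 1]^2 + rel[, 3]^2) * h^3
  base$`Iyy` <- sum(rel[, 2]^2 + rel[, 3]^2) * h^3
  base$`Izz` <- sum(rel[, 1]^2 + rel[, 2]^2) * h^3
  base
}

#' Tile a volume into matched rectangular analysis prisms
#'
#' An axis-aligned grid of `prism_size_um` boxes is anchored at the minimum
#' corner of the ROI bounding box (plus an optional offset); only prisms that
#' lie fully inside the ROI are retained.  Applying the same grid to the CT
#' and histology volumes (which share a frame after reconstruction) yields
#' matched per-prism samples.
#'
#' @param volume A [binary_volume()], [labeled_volume()] or 3D array (used
#'   for its dimensions).
#' @param spacing_um Voxel spacing (taken from the volume when available).
#' @param roi_mask Logical 3D array; defaults to the full volume.
#' @param prism_size_um Numeric length 3, default `c(512, 512, 230)`.
#' @param offset_vox Integer length-3 grid anchor offset in voxels.
#' @return Object of class `prism_grid`: `prisms` (tibble with 1-based
#'   origin indices `x0`, `y0`, `z0` and `prism` id), `size_vox`,
#'   `prism_size_um`, `count`.
#' @export
tile_volume_prisms <- function(volume, spacing_um = NULL, roi_mask = NULL,
                               prism_size_um = c(512, 512, 230),
                               offset_vox = c(0L, 0L, 0L)) {
  vox <- if (inherits(volume, "binary_volume")) volume$voxels
         else if (inherits(volume, "labeled_volume")) volume$voxels
         else volume
  spacing_um <- spacing_um %||%
    (if (inherits(volume, c("binary_volume", "labeled_volume"))) volume$spacing_um else
       abort("tile_volume_prisms: spacing_um required for plain arrays"))
  spacing_um <- rep_len(spacing_um, 3)
  d <- dim(vox)
  roi_mask <- roi_mask %||% array(TRUE, d)
  # prism size in voxels; order (row, col, plane) = (y, x, z) vs (x, y, z) input
  size_vox <- as.integer(floor(prism_size_um[c(2, 1, 3)] / spacing_um))
  if (any(size_vox < 1) || any(size_vox > d))
    abort("tile_volume_prisms: prism size exceeds the ROI extent")
  idx <- which(roi_mask, arr.ind = TRUE)
  if (!nrow(idx)) abort("tile_volume_prisms: empty ROI")
  lo <- apply(idx, 2, min) + offset_vox
  hi <- apply(idx, 2, max)
  starts <- lapply(1:3, function(a) {
    s <- seq(lo[a], hi[a] - size_vox[a] + 1L, by = size_vox[a])
    s[s >= 1]
  })
  if (any(lengths(starts) == 0)) abort("tile_volume_prisms: no prism fits inside the ROI")
  grid <- tidyr::expand_grid(y0 = starts[[1]], x0 = starts[[2]], z0 = starts[[3]])
  inside <- vapply(seq_len(nrow(grid)), function(i) {
    r <- grid$y0[i]:(grid$y0[i] + size_vox[1] - 1)
    c <- grid$x0[i]:(grid$x0[i] + size_vox[2] - 1)
    z <- grid$z0[i]:(grid$z0[i] + size_vox[3] - 1)
    all(roi_mask[r, c, z])
  }, logical(1))
  prisms <- grid[inside, ]
  if (!nrow(prisms)) abort("tile_volume_prisms: no prism fits inside the ROI")
  prisms$prism <- seq_len(nrow(prisms))
  structure(list(prisms = prisms, size_vox = size_vox,
                 prism_size_um = prism_size_um, count = nrow(prisms),
                 spacing_um = spacing_um),
            class = "prism_grid")
}

#' @export
print.prism_grid <- function(x, ...) {
  cat(sprintf("<prism_grid> %d prisms of %s um (%s voxels)\n", x$count,
              paste(x$prism_size_um, collapse = " x "),
              paste(x$size_vox, collapse = " x ")))
  invisible(x)
}

#' Per-prism morphometry table
#'
#' Runs [compute_morphometry()] on each prism of a [tile_volume_prisms()]
#' grid and binds the rows, keyed by prism id.
#'
#' @param bv A [binary_volume()] (or input for [binarize_volume()]).
#' @param grid A [prism_grid].
#' @param rule Binarization rule forwarded to [binarize_volume()].
#' @param ... Passed to [compute_morphometry()].
#' @return A tibble with one row per prism.
#' @export
morphometry_table <- function(bv, grid, rule = NULL, ...) {
  if (!inherits(bv, "binary_volume")) bv <- binarize_volume(bv, rule)
  stopifnot(inherits(grid, "prism_grid"))
  sv <- grid$size_vox
  rows <- purrr::pmap(grid$prisms, function(y0, x0, z0, prism) {
    sub <- bv$voxels[y0:(y0 + sv[1] - 1), x0:(x0 + sv[2] - 1),
                     z0:(z0 + sv[3] - 1), drop = FALSE]
    res <- compute_morphometry(binary_volume(sub, bv$spacing_um), ...)
    dplyr::bind_cols(tibble(prism = prism), res)
  })
  dplyr::bind_rows(rows)
}
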