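#' Labelled 3D tissue volume
#'
#' The common container for reconstructed and ground-truth volumes: a 3D grid
#' of integer tissue classes with (possibly anisotropic) voxel spacing.
#' Classes are 0 = non-mineralized tissue, 1 = bone, 2 = residual graft
#' material, 255 = missing slide plane.
#'
#' @param voxels 3D integer array (rows, cols, planes).
#' @param spacing_um Voxel spacing in micrometres, length 3 (row, col, plane).
#' @param frame Character tag naming the coordinate frame the volume is
#'   registered to (e.g. `"phantom"`, `"ct"`).
#' @param missing_planes Integer indices of planes with no slide (optional).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, spacing_um, frame = "phantom",
                           missing_planes = integer()) {
  if (length(dim(voxels)) != 3) abort("labeled_volume: `voxels` must be a 3D array")
  spacing_um <- rep_len(as.numeric(spacing_um), 3)
  if (any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    abort("labeled_volume: spacing must be positive")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing_um = spacing_um, frame = frame,
                 missing_planes = as.integer(missing_planes)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um, frame '%s'\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3], x$frame))
  tb <- table(x$voxels)
  cat("  classes:", paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  if (length(x$missing_planes))
    cat("  missing planes:", paste(x$missing_planes, collapse = ", "), "\n")
  invisible(x)
}

#' Binary (mineralized / background) volume
#'
#' @param voxels 3D logical array, `TRUE` = mineralized phase.
#' @param spacing_um Voxel spacing in micrometres (length 1 or 3).
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, spacing_um) {
  if (length(dim(voxels)) != 3) abort("binary_volume: `voxels` must be a 3D array")
  spacing_um <- rep_len(as.numeric(spacing_um), 3)
  if (any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    abort("binary_volume: spacing must be positive")
  v <- array(as.logical(voxels), dim(voxels))
  structure(list(voxels = v, spacing_um = spacing_um), class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um, fill %.1f%%\n",
              d[1], d[2], d[3], x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
              100 * mean(x$voxels)))
  invisible(x)
}

# evaluate code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
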