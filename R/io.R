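# Plain-raster I/O: numbered PNG slides, multi-page TIFF volumes, JSON
# sidecars for transforms and volume metadata, CSV morphometry tables.

#' Write a histology stack as numbered PNG slides with a JSON ground truth
#'
#' Transforms are serialized as `[tx, ty, theta_deg, scale]` with the
#' composition convention recorded in a header field; z indices are written
#' 0-based.
#'
#' @param stack A [simulate_histology_stack()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_histology_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "histology_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (key in names(stack$slides)) {
    p <- file.path(dir, sprintf("slide_%04d.png", as.integer(key)))
    png::writePNG(stack$slides[[key]], p)
    pm <- file.path(dir, sprintf("mask_%04d.png", as.integer(key)))
    png::writePNG(stack$masks[[key]] / 255, pm)
    paths <- c(paths, p, pm)
  }
  truth <- stack$truth
  sidecar <- list(
    convention = "affine = T(tx,ty) . R(theta) . S(s) about the image centre; z 0-based",
    pixel_ratio_um = stack$pixel_ratio_um,
    slides = lapply(seq_len(nrow(truth)), function(i) list(
      slide_id = truth$slide_id[i],
      z_index = truth$z_index[i] - 1L,
      transform = c(truth$tx[i], truth$ty[i], truth$theta[i], truth$s[i]),
      dropped = truth$dropped[i])))
  jp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read numbered PNG/TIFF slides from a directory
#'
#' @param dir Directory containing `slide_*.png`/`.tif` files.
#' @return Named list of image arrays, ordered by slide number.
#' @export
read_slides <- function(dir) {
  files <- sort(list.files(dir, pattern = "^slide_.*\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (!length(files)) abort(paste0("read_slides: no slide files in ", dir))
  out <- lapply(files, function(f) {
    if (grepl("png$", f)) png::readPNG(f) else tiff::readTIFF(f)
  })
  names(out) <- sub("^slide_0*", "", sub("\\.[a-z]+$", "", basename(files)))
  out
}

#' Write a volume (3D array or labelled volume) as multi-page TIFF + JSON
#'
#' @param vol A [labeled_volume()], [binary_volume()] or 3D numeric array in
#'   `[0, 1]`.
#' @param path Output TIFF path; metadata goes to `<path>.json`.
#' @param spacing_um Spacing for plain arrays.
#' @return Invisibly, `path`.
#' @export
write_volume_tiff <- function(vol, path, spacing_um = NULL) {
  if (inherits(vol, "labeled_volume")) {
    arr <- vol$voxels / 255
    meta <- list(kind = "labeled", spacing_um = vol$spacing_um, frame = vol$frame,
                 missing_planes = vol$missing_planes,
                 classes = "0 non-mineralized, 1 bone, 2 graft, 255 missing (stored /255)")
  } else if (inherits(vol, "binary_volume")) {
    arr <- vol$voxels * 1
    meta <- list(kind = "binary", spacing_um = vol$spacing_um)
  } else {
    arr <- vol
    meta <- list(kind = "grayscale", spacing_um = spacing_um)
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_volume_tiff()]
#'
#' @param path TIFF path.
#' @return A [labeled_volume()], [binary_volume()] or plain array, per the
#'   JSON sidecar (plain grayscale if no sidecar is found).
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  jp <- paste0(path, ".json")
  if (!file.exists(jp)) return(arr)
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  switch(meta$kind,
         labeled = labeled_volume(round(arr * 255), meta$spacing_um,
                                  frame = meta$frame %||% "unknown",
                                  missing_planes = meta$missing_planes %||% integer()),
         binary = binary_volume(arr > 0.5, meta$spacing_um),
         arr)
}

#' Write per-slide transforms as JSON
#'
#' @param transforms Tibble with columns `slide`, `tx`, `ty`, `theta`, `s`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(transforms, path) {
  obj <- list(convention = "affine = T(tx,ty) . R(theta) . S(s) about the image centre",
              transforms = lapply(seq_len(nrow(transforms)), function(i)
                list(slide = transforms$slide[i],
                     transform = c(transforms$tx[i], transforms$ty[i],
                                   transforms$theta[i], transforms$s[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
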