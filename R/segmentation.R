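# Tile-based three-class tissue segmentation: tiling with overlap, inverse
# frequency class weights, overlap-averaged stitching, bilateral smoothing
# and most-probable-class thresholding.

#' Split an image into overlapping tiles
#'
#' Tiles are `tile x tile` with `overlap` pixels of overlap in each
#' direction (stride `tile - overlap`); border tiles are shifted inward so
#' every tile is full-sized.  Images smaller than one tile are reflect-padded.
#'
#' @param image Matrix or H x W x C array.
#' @param tile Tile edge length (default 512).
#' @param overlap Overlap in pixels (default 64).
#' @return List of class `tileset`: `tiles` (list), `origins` (tibble row,
#'   col, 1-based), `tile`, `overlap`, `parent_shape`, `padded_shape`.
#' @export
tile_image <- function(image, tile = 512, overlap = 64) {
  dims <- if (is.matrix(image)) c(dim(image), 1L) else dim(image)
  parent_shape <- dims[1:2]
  pad_to <- pmax(parent_shape, tile)
  if (any(pad_to > parent_shape)) {
    image <- reflect_pad(image, pad_to)
  }
  sz <- pad_to
  stride <- tile - overlap
  origins_axis <- function(n) {
    o <- seq(1, max(1, n - tile + 1), by = stride)
    if (tail(o, 1) + tile - 1 < n) o <- c(o, n - tile + 1)
    unique(o)
  }
  orow <- origins_axis(sz[1]); ocol <- origins_axis(sz[2])
  origins <- tidyr::expand_grid(row = orow, col = ocol)
  tiles <- purrr::pmap(origins, function(row, col) {
    if (is.matrix(image)) image[row:(row + tile - 1), col:(col + tile - 1)]
    else image[row:(row + tile - 1), col:(col + tile - 1), , drop = FALSE]
  })
  structure(list(tiles = tiles, origins = origins, tile = tile,
                 overlap = overlap, parent_shape = parent_shape,
                 padded_shape = sz),
            class = "tileset")
}

reflect_pad <- function(image, pad_to) {
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  ridx <- reflect_indices(dims[1], pad_to[1])
  cidx <- reflect_indices(dims[2], pad_to[2])
  if (is.matrix(image)) image[ridx, cidx] else image[ridx, cidx, , drop = FALSE]
}

reflect_indices <- function(n, m) {
  idx <- seq_len(m)
  period <- max(2 * n - 2, 1)
  r <- (idx - 1) %% period
  ifelse(r < n, r + 1, 2 * n - r - 1)
}

#' @export
print.tileset <- function(x, ...) {
  cat(sprintf("<tileset> %d tiles of %d px (overlap %d) covering %s\n",
              length(x$tiles), x$tile, x$overlap,
              paste(x$parent_shape, collapse = " x ")))
  invisible(x)
}

#' Stitch per-tile maps back into the parent frame, averaging overlaps
#'
#' @param tiles List of tile-shaped matrices or H x W x C arrays (e.g.
#'   probability maps), in the order of `tileset$origins`.
#' @param tileset The [tile_image()] result the tiles came from.
#' @return Matrix or array on the parent image shape.
#' @export
stitch_tiles <- function(tiles, tileset) {
  sz <- tileset$padded_shape
  t1 <- tiles[[1]]
  nch <- if (is.matrix(t1)) 1L else dim(t1)[3]
  acc <- array(0, c(sz, nch))
  wgt <- matrix(0, sz[1], sz[2])
  tl <- tileset$tile
  for (i in seq_along(tiles)) {
    r <- tileset$origins$row[i]; c <- tileset$origins$col[i]
    rows <- r:(r + tl - 1); cols <- c:(c + tl - 1)
    ti <- tiles[[i]]
    if (is.matrix(ti)) ti <- array(ti, c(dim(ti), 1))
    acc[rows, cols, ] <- acc[rows, cols, , drop = FALSE] + ti
    wgt[rows, cols] <- wgt[rows, cols] + 1
  }
  for (ch in seq_len(nch)) acc[, , ch] <- acc[, , ch] / wgt
  out <- acc[seq_len(tileset$parent_shape[1]), seq_len(tileset$parent_shape[2]), ,
             drop = FALSE]
  if (nch == 1) matrix(out, tileset$parent_shape[1], tileset$parent_shape[2]) else out
}

#' Inverse-frequency class weights from ground-truth masks
#'
#' `weight_c = N_total / (n_classes * N_c)`: balanced masks give unit
#' weights, rare classes get proportionally larger ones, and the weights are
#' invariant to dataset size.
#'
#' @param masks List of integer class masks (values 0, 1, 2) or one mask.
#' @param classes Class labels expected present.
#' @return Named numeric vector of weights (nonmineralized, bone, graft).
#' @export
compute_class_weights <- function(masks, classes = 0:2) {
  if (!is.list(masks)) masks <- list(masks)
  counts <- vapply(classes, function(cl)
    sum(vapply(masks, function(m) sum(m == cl), numeric(1))), numeric(1))
  names(counts) <- c("nonmineralized", "bone", "graft")[match(classes, 0:2)]
  absent <- counts == 0
  if (any(absent))
    abort(paste0("compute_class_weights: class(es) absent from masks: ",
                 paste(names(counts)[absent], collapse = ", ")))
  total <- sum(counts)
  total / (length(classes) * counts)
}

#' Smooth a probability map and threshold to the most probable class
#'
#' Bilateral filtering is applied to each probability channel independently
#' (window `filter_size`, standard deviation `sigma_color` in value space on
#' the usual 8-bit scale and `sigma_space` in pixel space); unlike a Gaussian
#' blur it removes isolated network artifacts without displacing class
#' edges.  Probabilities are renormalized, then each pixel is assigned its
#' most probable class; exact ties are broken by the fixed priority
#' bone > graft > non-mineralized.
#'
#' @param prob_map H x W x 3 array of class probabilities in channel order
#'   (non-mineralized, bone, graft); rows sum to 1.
#' @param filter_size Bilateral window size in pixels.
#' @param sigma_color Value-space standard deviation on a 0--255 scale.
#' @param sigma_space Pixel-space standard deviation.
#' @return List: `class_mask` (integer matrix, values 0/1/2), `prob_map`
#'   (the filtered, renormalized probabilities).
#' @export
postprocess_probabilities <- function(prob_map, filter_size = 32,
                                      sigma_color = 64, sigma_space = 64) {
  stopifnot(length(dim(prob_map)) == 3, dim(prob_map)[3] == 3)
  radius <- max(1L, as.integer(filter_size / 2))
  sc <- sigma_color / 255  # probabilities live on [0, 1]
  sm <- prob_map
  for (ch in 1:3) sm[, , ch] <- cpp_bilateral(prob_map[, , ch], radius, sc, sigma_space)
  tot <- sm[, , 1] + sm[, , 2] + sm[, , 3]
  for (ch in 1:3) sm[, , ch] <- sm[, , ch] / tot
  # argmax with tie priority bone (1) > graft (2) > non-mineralized (0)
  pb <- sm[, , 2]; pg <- sm[, , 3]; pn <- sm[, , 1]
  cls <- matrix(0L, nrow(pb), ncol(pb))
  cls[pg >= pn] <- 2L                 # graft beats non-mineralized on ties
  cls[pb >= pg & pb >= pn] <- 1L      # bone beats everything on ties
  list(class_mask = cls, prob_map = sm)
}
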