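# A small configurable U-Net: encoder-decoder with skip concatenations,
# batch normalization inside the 3x3 convolution blocks, dropout after the
# concatenations, class-weighted categorical cross-entropy, Adam, and a
# plateau learning-rate schedule.  Forward and backward passes are written
# against the compiled conv / pool / transposed-conv kernels in src/.

#' Configuration of the segmentation network
#'
#' The `"full"` preset is the full-scale configuration for real slide scans:
#' 512-pixel tiles with
#' 64-pixel overlap, four 2x2 pooling levels (so the bottleneck feature map
#' is 32 x 32), batch size 16, 5% dropout, 200 epochs with a learning rate
#' starting at 1e-3 and dropping by a factor of 10 (floor 1e-5) when the
#' validation loss stalls for 30 epochs, and five folds.  The `"tiny"` preset
#' is a desk-scale analogue used throughout the test suite: 32-pixel tiles,
#' two pooling levels, 8 base channels and 20 epochs, small enough to train
#' on a CPU in seconds.
#'
#' @param preset `"tiny"` (default) or `"full"`; individual fields can be
#'   overridden.
#' @param ... Overrides: `tile`, `overlap`, `depth`, `base_channels`,
#'   `dropout_rate`, `batch_size`, `epochs`, `lr_start`, `lr_floor`,
#'   `lr_factor`, `patience`, `folds`, `seed`.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(preset = c("tiny", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    full = list(tile = 512L, overlap = 64L, depth = 4L, base_channels = 16L,
                 dropout_rate = 0.05, batch_size = 16L, epochs = 200L,
                 lr_start = 1e-3, lr_floor = 1e-5, lr_factor = 10,
                 patience = 30L, folds = 5L, seed = 1L),
    tiny = list(tile = 32L, overlap = 8L, depth = 2L, base_channels = 8L,
                dropout_rate = 0.05, batch_size = 8L, epochs = 20L,
                lr_start = 3e-3, lr_floor = 1e-5, lr_factor = 10,
                patience = 8L, folds = 5L, seed = 1L))
  cfg <- modifyList(cfg, list(...))
  cfg$preset <- preset
  if (cfg$tile %% (2^cfg$depth) != 0)
    abort(sprintf("unet_config: input size %d not divisible by %d (2^depth)",
                  cfg$tile, 2^cfg$depth))
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    abort("unet_config: dropout_rate must lie in [0, 1)")
  if (cfg$lr_floor > cfg$lr_start) abort("unet_config: lr_floor must be <= lr_start")
  structure(cfg, class = "unet_config")
}

#' @export
print.unet_config <- function(x, ...) {
  cat(sprintf("<unet_config '%s'> tile %d, depth %d, base %d ch, batch %d, %d epochs\n",
              x$preset, x$tile, x$depth, x$base_channels, x$batch_size, x$epochs))
  invisible(x)
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)

new_bn <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch),
                            run_mean = rep(0, ch), run_var = rep(1, ch))

new_block <- function(cin, cout) {
  list(w1 = he_init(c(3, 3, cin, cout), 9 * cin), b1 = rep(0, cout), bn1 = new_bn(cout),
       w2 = he_init(c(3, 3, cout, cout), 9 * cout), b2 = rep(0, cout), bn2 = new_bn(cout))
}

#' Initialise network weights
#'
#' @param cfg A [unet_config()].
#' @param in_channels Input channels (3 for RGB tiles).
#' @param n_classes Output classes (3 tissue classes).
#' @param seed RNG seed for the He-normal initialisation.
#' @return An object of class `unet_model`.
#' @export
unet_init <- function(cfg, in_channels = 3, n_classes = 3, seed = cfg$seed) {
  ch <- cfg$base_channels * 2^(0:cfg$depth)
  with_seed(seed, {
    enc <- lapply(seq_len(cfg$depth), function(l)
      new_block(if (l == 1) in_channels else ch[l - 1], ch[l]))
    bott <- new_block(ch[cfg$depth], ch[cfg$depth + 1])
    dec <- lapply(seq_len(cfg$depth), function(l)
      c(list(wt = he_init(c(2, 2, ch[l + 1], ch[l]), 4 * ch[l + 1]), bt = rep(0, ch[l])),
        new_block(2 * ch[l], ch[l])))
    out <- list(w = he_init(c(ch[1], n_classes), ch[1]), b = rep(0, n_classes))
    structure(list(enc = enc, bott = bott, dec = dec, out = out,
                   cfg = cfg, in_channels = in_channels, n_classes = n_classes),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  bs <- unet_bottleneck_shape(x)
  cat(sprintf("<unet_model> depth %d, %d -> %d channels, %d x %d input, %d x %d bottleneck\n",
              x$cfg$depth, x$in_channels, x$n_classes, x$cfg$tile, x$cfg$tile,
              bs[1], bs[2]))
  invisible(x)
}

#' Bottleneck feature-map resolution of a constructed model
#'
#' Walks the model's actual encoder levels, halving the tile resolution at
#' each pooling step, and returns the spatial size at which the bottleneck
#' block operates (e.g. 32 x 32 for 512-pixel input with four poolings).
#'
#' @param model A [unet_init()] model.
#' @return Integer vector (rows, cols) of the bottleneck feature map.
#' @export
unet_bottleneck_shape <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sz <- c(model$cfg$tile, model$cfg$tile)
  for (l in seq_along(model$enc)) sz <- sz %/% 2L
  sz
}

# ---- layers -----------------------------------------------------------------

bn_forward <- function(x, p, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  y <- x
  cache <- list(xhat = NULL, mu = NULL, var = NULL, p = p, eps = eps)
  if (train) {
    mu <- numeric(C); va <- numeric(C)
    xhat <- x
    for (c in seq_len(C)) {
      xc <- x[, , c, , drop = FALSE]
      mu[c] <- mean(xc)
      va[c] <- mean((xc - mu[c])^2)
      xhat[, , c, ] <- (xc - mu[c]) / sqrt(va[c] + eps)
      y[, , c, ] <- p$gamma[c] * xhat[, , c, , drop = FALSE] + p$beta[c]
    }
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * va
    cache$xhat <- xhat; cache$mu <- mu; cache$var <- va
  } else {
    for (c in seq_len(C)) {
      y[, , c, ] <- p$gamma[c] * (x[, , c, , drop = FALSE] - p$run_mean[c]) /
        sqrt(p$run_var[c] + eps) + p$beta[c]
    }
  }
  list(y = y, cache = cache, p = p)
}

bn_backward <- function(dy, cache) {
  d <- dim(dy); C <- d[3]
  m <- prod(d[-3])
  dx <- dy
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    g <- cache$p$gamma[c]
    xh <- cache$xhat[, , c, , drop = FALSE]
    dyc <- dy[, , c, , drop = FALSE]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    istd <- 1 / sqrt(cache$var[c] + cache$eps)
    dxhat <- dyc * g
    dx[, , c, ] <- istd * (dxhat - mean(dxhat) - xh * mean(dxhat * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

block_forward <- function(x, p, train) {
  c1 <- cpp_conv3_fwd(x, p$w1, p$b1)
  b1 <- bn_forward(c1, p$bn1, train)
  r1 <- pmax(b1$y, 0)
  c2 <- cpp_conv3_fwd(r1, p$w2, p$b2)
  b2 <- bn_forward(c2, p$bn2, train)
  r2 <- pmax(b2$y, 0)
  list(y = r2, cache = list(x = x, b1 = b1$cache, r1 = r1, b2 = b2$cache,
                            a1 = b1$y, a2 = b2$y, p = p),
       p_bn = list(bn1 = b1$p, bn2 = b2$p))
}

block_backward <- function(dy, cache) {
  p <- cache$p
  dy <- dy * (cache$a2 > 0)
  bb2 <- bn_backward(dy, cache$b2)
  g2 <- cpp_conv3_bwd(cache$r1, p$w2, bb2$dx)
  dr1 <- g2$dx * (cache$a1 > 0)
  bb1 <- bn_backward(dr1, cache$b1)
  g1 <- cpp_conv3_bwd(cache$x, p$w1, bb1$dx)
  list(dx = g1$dx,
       grads = list(w1 = g1$dw, b1 = g1$db,
                    bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                    w2 = g2$dw, b2 = g2$db,
                    bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta)))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  skips <- list(); caches <- list(enc = list(), dec = list())
  h <- x
  for (l in seq_len(cfg$depth)) {
    bf <- block_forward(h, model$enc[[l]], train)
    model$enc[[l]]$bn1 <- bf$p_bn$bn1; model$enc[[l]]$bn2 <- bf$p_bn$bn2
    skips[[l]] <- bf$y
    caches$enc[[l]] <- bf$cache
    mp <- cpp_maxpool2_fwd(bf$y)
    caches$enc[[l]]$pool_arg <- mp$argmax
    caches$enc[[l]]$pool_in_dim <- dim(bf$y)
    h <- mp$y
  }
  bf <- block_forward(h, model$bott, train)
  model$bott$bn1 <- bf$p_bn$bn1; model$bott$bn2 <- bf$p_bn$bn2
  caches$bott <- bf$cache
  h <- bf$y
  for (l in rev(seq_len(cfg$depth))) {
    p <- model$dec[[l]]
    up <- cpp_tconv2_fwd(h, p$wt, p$bt)
    cat_in <- concat_ch(up, skips[[l]])
    drop_mask <- NULL
    if (train && cfg$dropout_rate > 0) {
      drop_mask <- array((runif(length(cat_in)) >= cfg$dropout_rate) /
                           (1 - cfg$dropout_rate), dim(cat_in))
      cat_in <- cat_in * drop_mask
    }
    bf <- block_forward(cat_in, p, train)
    model$dec[[l]]$bn1 <- bf$p_bn$bn1; model$dec[[l]]$bn2 <- bf$p_bn$bn2
    caches$dec[[l]] <- list(tconv_in = h, up_ch = dim(up)[3], block = bf$cache,
                            drop_mask = drop_mask)
    h <- bf$y
  }
  d <- dim(h)
  hm <- matrix(aperm(h, c(1, 2, 4, 3)), ncol = d[3])
  logits_m <- sweep(hm %*% model$out$w, 2, model$out$b, FUN = "+")
  K <- ncol(logits_m)
  logits <- aperm(array(logits_m, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  mx <- apply(logits, c(1, 2, 4), max)  # (H, W, N)
  ex <- logits
  for (k in seq_len(K)) ex[, , k, ] <- exp(array(logits[, , k, ], dim(mx)) - mx)
  tot <- ex[, , 1, , drop = FALSE]
  for (k in 2:K) tot <- tot + ex[, , k, , drop = FALSE]
  probs <- ex
  for (k in seq_len(K)) probs[, , k, ] <- ex[, , k, , drop = FALSE] / tot
  list(probs = probs, logits = logits, head_in = h,
       caches = caches, model = model)
}

# Class-weighted categorical cross-entropy; y is an integer array (H, W, N)
# with classes 0..K-1.  Returns loss and d(loss)/d(logits).
weighted_ce <- function(probs, y, class_weights) {
  d <- dim(probs); K <- d[3]
  wpix <- array(class_weights[as.vector(y) + 1], dim(y))
  wsum <- sum(wpix)
  loss <- 0
  dlogits <- probs
  for (k in seq_len(K)) {
    is_k <- array(as.numeric(y == (k - 1)), dim(y))
    pk <- array(probs[, , k, ], dim(y))
    loss <- loss - sum(wpix * is_k * log(pmax(pk, 1e-12)))
    dlogits[, , k, ] <- (pk - is_k) * wpix / wsum
  }
  list(loss = loss / wsum, dlogits = dlogits)
}

unet_backward <- function(fwd, dlogits) {
  model <- fwd$model; cfg <- model$cfg
  grads <- list(enc = vector("list", cfg$depth), dec = vector("list", cfg$depth))
  d <- dim(fwd$head_in)
  K <- dim(dlogits)[3]
  dl_m <- matrix(aperm(dlogits, c(1, 2, 4, 3)), ncol = K)
  hm <- matrix(aperm(fwd$head_in, c(1, 2, 4, 3)), ncol = d[3])
  grads$out <- list(w = t(hm) %*% dl_m, b = colSums(dl_m))
  dh_m <- dl_m %*% t(model$out$w)
  dh <- aperm(array(dh_m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  for (l in seq_len(cfg$depth)) {
    cc <- fwd$caches$dec[[l]]
    bb <- block_backward(dh, cc$block)
    dcat <- bb$dx
    if (!is.null(cc$drop_mask)) dcat <- dcat * cc$drop_mask
    nu <- cc$up_ch
    dup <- dcat[, , seq_len(nu), , drop = FALSE]
    dskip <- dcat[, , nu + seq_len(dim(dcat)[3] - nu), , drop = FALSE]
    gt <- cpp_tconv2_bwd(cc$tconv_in, model$dec[[l]]$wt, dup)
    grads$dec[[l]] <- c(list(wt = gt$dw, bt = gt$db), bb$grads)
    grads$dec[[l]]$dskip <- dskip
    dh <- gt$dx
  }
  bb <- block_backward(dh, fwd$caches$bott)
  grads$bott <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(cfg$depth))) {
    cc <- fwd$caches$enc[[l]]
    dpool <- cpp_maxpool2_bwd(dh, cc$pool_arg, cc$pool_in_dim)
    dtotal <- dpool + grads$dec[[l]]$dskip
    grads$dec[[l]]$dskip <- NULL
    bb <- block_backward(dtotal, cc)
    grads$enc[[l]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

# ---- Adam over the nested parameter list ------------------------------------

numeric_leaves <- function(x, path = character()) {
  if (is.numeric(x)) return(stats::setNames(list(x), paste(path, collapse = "|")))
  if (is.list(x)) {
    out <- list()
    keys <- names(x) %||% rep("", length(x))
    for (i in seq_along(x)) {
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      if (key %in% c("run_mean", "run_var", "cfg", "in_channels", "n_classes")) next
      out <- c(out, numeric_leaves(x[[i]], c(path, key)))
    }
    return(out)
  }
  list()
}

path_part <- function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p

leaf_get <- function(x, path) {
  for (p in path) {
    x <- x[[path_part(p)]]
    if (is.null(x)) return(NULL)
  }
  x
}

leaf_set <- function(x, path, value) {
  p <- path_part(path[1])
  if (length(path) == 1) { x[[p]] <- value; return(x) }
  x[[p]] <- leaf_set(x[[p]], path[-1], value)
  x
}

adam_state <- function(model) {
  leaves <- numeric_leaves(unclass(model)[c("enc", "bott", "dec", "out")])
  list(m = lapply(leaves, function(v) v * 0),
       v = lapply(leaves, function(v) v * 0),
       t = 0, paths = lapply(names(leaves), function(nm) strsplit(nm, "|", fixed = TRUE)[[1]]))
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  core <- unclass(model)[c("enc", "bott", "dec", "out")]
  for (i in seq_along(state$paths)) {
    path <- state$paths[[i]]
    g <- leaf_get(grads, path)
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    val <- leaf_get(core, path) - lr * mhat / (sqrt(vhat) + eps)
    core <- leaf_set(core, path, val)
  }
  for (nm in names(core)) model[[nm]] <- core[[nm]]
  list(model = model, state = state)
}

# ---- training ---------------------------------------------------------------

tiles_to_batch <- function(tiles, idx) {
  t1 <- tiles[[idx[1]]]
  if (is.matrix(t1)) t1 <- array(t1, c(dim(t1), 1))
  d <- dim(t1)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (i in seq_along(idx)) {
    ti <- tiles[[idx[i]]]
    if (is.matrix(ti)) ti <- array(ti, c(dim(ti), 1))
    x[, , , i] <- ti
  }
  x
}

masks_to_batch <- function(masks, idx) {
  d <- dim(masks[[idx[1]]])
  y <- array(0L, c(d[1], d[2], length(idx)))
  for (i in seq_along(idx)) y[, , i] <- masks[[idx[i]]]
  y
}

#' Plateau learning-rate schedule
#'
#' Given a sequence of validation losses, returns the learning rate in force
#' at each epoch: starting from `lr_start`, divided by `lr_factor` whenever
#' the validation loss has not improved for `patience` consecutive epochs,
#' floored at `lr_floor`.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param cfg A [unet_config()].
#' @return Numeric vector of learning rates, one per epoch.
#' @export
lr_schedule_trace <- function(val_losses, cfg) {
  lr <- cfg$lr_start
  best <- Inf; since <- 0L
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    out[e] <- lr
    if (val_losses[e] < best - 1e-12) { best <- val_losses[e]; since <- 0L }
    else {
      since <- since + 1L
      if (since >= cfg$patience) { lr <- max(lr / cfg$lr_factor, cfg$lr_floor); since <- 0L }
    }
  }
  out
}

eval_model <- function(model, tiles, masks, idx, class_weights, batch) {
  tot_loss <- 0; tot_correct <- 0; tot_pix <- 0; nb <- 0
  for (start in seq(1, length(idx), by = batch)) {
    ii <- idx[start:min(start + batch - 1, length(idx))]
    x <- tiles_to_batch(tiles, ii); y <- masks_to_batch(masks, ii)
    fwd <- unet_forward(model, x, train = FALSE)
    l <- weighted_ce(fwd$probs, y, class_weights)
    tot_loss <- tot_loss + l$loss; nb <- nb + 1
    pred <- apply(fwd$probs, c(1, 2, 4), which.max) - 1L
    tot_correct <- tot_correct + sum(pred == y)
    tot_pix <- tot_pix + length(y)
  }
  list(loss = tot_loss / nb, accuracy = tot_correct / tot_pix)
}

#' Train the network on a train/validation split
#'
#' @param tiles List of H x W x 3 tiles (values in `[0, 1]`).
#' @param masks List of matching integer class masks.
#' @param idx_train,idx_val Index vectors into `tiles`.
#' @param cfg A [unet_config()].
#' @param class_weights Named weights from [compute_class_weights()];
#'   computed from the training masks when `NULL`.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return An object of class `unet_model` with an added `history` tibble
#'   (epoch, lr, train_loss, val_loss, val_accuracy).
#' @export
train_unet <- function(tiles, masks, idx_train, idx_val, cfg,
                       class_weights = NULL, seed = cfg$seed) {
  class_weights <- class_weights %||% compute_class_weights(masks[idx_train])
  model <- unet_init(cfg, in_channels = 3, n_classes = 3, seed = seed)
  state <- adam_state(model)
  lr <- cfg$lr_start
  best <- Inf; since <- 0L
  hist <- vector("list", cfg$epochs)
  with_seed(seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(idx_train)
      train_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        ii <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        x <- tiles_to_batch(tiles, ii); y <- masks_to_batch(masks, ii)
        fwd <- unet_forward(model, x, train = TRUE)
        model <- fwd$model  # running BN stats updated
        l <- weighted_ce(fwd$probs, y, class_weights)
        if (!is.finite(l$loss))
          abort(sprintf("train_unet: non-finite loss at epoch %d (lr %.2g, batch of %d); aborting",
                        epoch, lr, length(ii)))
        grads <- unet_backward(fwd, l$dlogits)
        st <- adam_step(model, grads, state, lr)
        model <- st$model; state <- st$state
        train_loss <- train_loss + l$loss; nb <- nb + 1
      }
      ev <- eval_model(model, tiles, masks, idx_val, class_weights, cfg$batch_size)
      hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                              train_loss = train_loss / nb,
                              val_loss = ev$loss, val_accuracy = ev$accuracy)
      if (ev$loss < best - 1e-12) { best <- ev$loss; since <- 0L }
      else {
        since <- since + 1L
        if (since >= cfg$patience) { lr <- max(lr / cfg$lr_factor, cfg$lr_floor); since <- 0L }
      }
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model$class_weights <- class_weights
  model
}

#' Five-fold cross-validated training
#'
#' Tiles are partitioned into `cfg$folds` equal folds (deterministically for
#' a fixed `cfg$seed`); each model trains on the remaining folds and
#' validates on its own, and the resulting models form the prediction
#' ensemble.  Class weights are recomputed from each fold's training masks.
#'
#' @param tiles,masks Lists of tiles and matching class masks.
#' @param cfg A [unet_config()].
#' @return An object of class `unet_ensemble`: `models`, `folds` (tibble:
#'   fold, n_val, val_accuracy), `cfg`.
#' @export
train_kfold <- function(tiles, masks, cfg = unet_config()) {
  n <- length(tiles)
  if (n < cfg$folds) abort("train_kfold: need at least as many tiles as folds")
  fold_of <- with_seed(cfg$seed, sample(rep(seq_len(cfg$folds), length.out = n)))
  models <- vector("list", cfg$folds)
  rows <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    idx_val <- which(fold_of == f)
    idx_train <- which(fold_of != f)
    m <- train_unet(tiles, masks, idx_train, idx_val, cfg, seed = cfg$seed + f)
    models[[f]] <- m
    rows[[f]] <- tibble(fold = f, n_val = length(idx_val),
                        val_accuracy = tail(m$history$val_accuracy, 1))
  }
  structure(list(models = models, folds = dplyr::bind_rows(rows),
                 fold_of = fold_of, cfg = cfg),
            class = "unet_ensemble")
}

#' @export
print.unet_ensemble <- function(x, ...) {
  cat(sprintf("<unet_ensemble> %d fold models, val accuracy %s\n",
              length(x$models),
              paste(sprintf("%.4f", x$folds$val_accuracy), collapse = ", ")))
  invisible(x)
}

#' Predict a whole slide in one forward pass
#'
#' The network is fully convolutional, so a whole working image can be pushed
#' through in a single pass (reflect-padded to a multiple of `2^depth`),
#' which avoids redundant overlap computation; tile-based
#' [predict_ensemble()] remains the route for images too large to hold in
#' memory at once.
#'
#' @param image H x W x 3 array.
#' @param ensemble A [train_kfold()] result (or list of models).
#' @return H x W x 3 probability array.
#' @export
predict_slide <- function(image, ensemble) {
  models <- if (inherits(ensemble, "unet_ensemble")) ensemble$models else ensemble
  if (!length(models)) abort("predict_slide: empty ensemble")
  depth <- if (inherits(ensemble, "unet_ensemble")) ensemble$cfg$depth
           else purrr::detect(models, inherits, "unet_model")$cfg$depth
  div <- 2^depth
  d <- dim(image)
  pad_to <- ceiling(d[1:2] / div) * div
  padded <- reflect_pad(image, pad_to)
  x <- array(padded, c(dim(padded)[1:2], d[3], 1))
  acc <- NULL
  for (mdl in models) {
    p <- if (is.function(mdl)) mdl(padded) else {
      fwd <- unet_forward(mdl, x, train = FALSE)
      array(fwd$probs[, , , 1], dim(fwd$probs)[1:3])
    }
    acc <- if (is.null(acc)) p else acc + p
  }
  pm <- acc[seq_len(d[1]), seq_len(d[2]), , drop = FALSE] / length(models)
  tot <- pm[, , 1] + pm[, , 2] + pm[, , 3]
  for (ch in 1:3) pm[, , ch] <- pm[, , ch] / tot
  pm
}

predict_tile <- function(model, tile_arr) {
  if (is.function(model)) return(model(tile_arr))
  x <- array(tile_arr, c(dim(tile_arr)[1:2], dim(tile_arr)[3], 1))
  fwd <- unet_forward(model, x, train = FALSE)
  array(fwd$probs[, , , 1], dim(fwd$probs)[1:3])
}

#' Predict a per-pixel class probability map with the fold ensemble
#'
#' The image is tiled like the training data, each tile is pushed through
#' every fold model, the per-model softmax outputs are averaged, tiles are
#' stitched with overlap averaging, and the result is renormalized so each
#' pixel's three probabilities sum to one.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param ensemble A [train_kfold()] result (stub models — plain functions
#'   mapping a tile to a probability array — are accepted, which the test
#'   suite uses).
#' @param tile,overlap Tiling geometry; defaults from the ensemble config.
#' @return H x W x 3 probability array (channels: non-mineralized, bone,
#'   graft).
#' @export
predict_ensemble <- function(image, ensemble, tile = NULL, overlap = NULL) {
  models <- if (inherits(ensemble, "unet_ensemble")) ensemble$models else ensemble
  if (!length(models)) abort("predict_ensemble: empty ensemble")
  cfg <- if (inherits(ensemble, "unet_ensemble")) ensemble$cfg else NULL
  tile <- tile %||% (cfg$tile %||% 512L)
  overlap <- overlap %||% (cfg$overlap %||% 64L)
  first_real <- purrr::detect(models, inherits, "unet_model")
  if (!is.null(first_real) && dim(image)[3] != first_real$in_channels)
    abort("predict_ensemble: image channel count does not match the trained model")
  ts <- tile_image(image, tile, overlap)
  prob_tiles <- lapply(ts$tiles, function(tl) {
    acc <- NULL
    for (m in models) {
      p <- predict_tile(m, tl)
      acc <- if (is.null(acc)) p else acc + p
    }
    acc / length(models)
  })
  pm <- stitch_tiles(prob_tiles, ts)
  tot <- pm[, , 1] + pm[, , 2] + pm[, , 3]
  for (ch in 1:3) pm[, , ch] <- pm[, , ch] / tot
  pm
}
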