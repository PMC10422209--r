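# The twin-channel encoder: a weight-sharing residual convolutional
# backbone, global average pooling to the feature vector, and a projection
# head onto the 128-dimensional unit hypersphere.
#
# "Twin-channel" is purely architectural bookkeeping: there is exactly one
# parameter set, applied to whichever input enters either channel, so the
# two channels cannot diverge by construction.

#' Encoder configuration
#'
#' @param backbone_depth `"small"` (stem + 2 residual stages; desk-scale
#'   CPU training) or `"standard"` (stem + 4 residual stages of 2 blocks,
#'   an 18-layer-class residual network).
#' @param feature_dim width of the pooled feature vector (default 1024).
#' @param projection_dim embedding dimension (default 128).
#' @param projection_layers 1 (single linear map, the default) or 2
#'   (linear-ReLU-linear, SimCLR-style).
#' @param projection_bias logical; a bias-free head (default) makes the
#'   embedding invariant to positive rescaling of the feature vector.
#' @param seed integer seed for weight initialization.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(backbone_depth = c("small", "standard"),
                           feature_dim = 1024L,
                           projection_dim = 128L,
                           projection_layers = 1L,
                           projection_bias = FALSE,
                           seed = 1L) {
  backbone_depth <- match.arg(backbone_depth)
  stopifnot_scalar_number(feature_dim, "feature_dim", TRUE)
  stopifnot_scalar_number(projection_dim, "projection_dim", TRUE)
  if (!projection_layers %in% c(1L, 2L)) {
    stop("projection_layers must be 1 or 2", call. = FALSE)
  }
  structure(list(
    backbone_depth = backbone_depth,
    feature_dim = as.integer(feature_dim),
    projection_dim = as.integer(projection_dim),
    projection_layers = as.integer(projection_layers),
    projection_bias = isTRUE(projection_bias),
    seed = as.integer(seed)
  ), class = "encoder_config")
}

encoder_arch <- function(config) {
  switch(config$backbone_depth,
    small = list(stem_ch = 8L, stages = list(
      list(ch = 8L, blocks = 1L),
      list(ch = 16L, blocks = 1L)
    )),
    standard = list(stem_ch = 16L, stages = list(
      list(ch = 16L, blocks = 2L),
      list(ch = 32L, blocks = 2L),
      list(ch = 64L, blocks = 2L),
      list(ch = 128L, blocks = 2L)
    ))
  )
}

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

#' Build a randomly initialized encoder
#'
#' The network is: 3x3 stem convolution, ReLU, 2x2 average pool; a sequence
#' of residual stages (each block is conv-ReLU-conv plus an identity or 1x1
#' projection skip, ReLU after the sum; 2x2 average pool between stages); a
#' 1x1 convolution widening to `feature_dim` channels, ReLU, and global
#' average pooling (the classification layer of a standard residual net is
#' absent); then the projection head and L2 normalization. Adaptive pooling
#' means any input side length >= 32 is accepted.
#'
#' @param config an [encoder_config()].
#' @return an object of class `odss_encoder`.
#' @export
build_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  arch <- encoder_arch(config)
  p <- list()
  with_seed(derive_seed(config$seed, "encoder-init"), {
    cin <- 1L
    ch <- arch$stem_ch
    p[["stem.W"]] <- matrix(he_init(9L * cin, 9L * cin * ch), 9L * cin, ch)
    p[["stem.b"]] <- numeric(ch)
    cin <- ch
    for (si in seq_along(arch$stages)) {
      st <- arch$stages[[si]]
      for (bi in seq_len(st$blocks)) {
        pre <- sprintf("s%d.b%d", si, bi)
        p[[paste0(pre, ".conv1.W")]] <-
          matrix(he_init(9L * cin, 9L * cin * st$ch), 9L * cin, st$ch)
        p[[paste0(pre, ".conv1.b")]] <- numeric(st$ch)
        p[[paste0(pre, ".conv2.W")]] <-
          matrix(he_init(9L * st$ch, 9L * st$ch * st$ch), 9L * st$ch, st$ch)
        p[[paste0(pre, ".conv2.b")]] <- numeric(st$ch)
        if (cin != st$ch) {
          p[[paste0(pre, ".skip.W")]] <-
            matrix(he_init(cin, cin * st$ch), cin, st$ch)
          p[[paste0(pre, ".skip.b")]] <- numeric(st$ch)
        }
        cin <- st$ch
      }
    }
    p[["head.W"]] <- matrix(he_init(cin, cin * config$feature_dim),
                            cin, config$feature_dim)
    p[["head.b"]] <- numeric(config$feature_dim)
    d <- config$feature_dim
    if (config$projection_layers == 2L) {
      p[["proj1.W"]] <- matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
      p[["proj1.b"]] <- numeric(d)
    }
    p[["proj.W"]] <- matrix(stats::rnorm(d * config$projection_dim,
                                         sd = sqrt(1 / d)),
                            d, config$projection_dim)
    if (config$projection_bias) p[["proj.b"]] <- numeric(config$projection_dim)
  })
  structure(list(config = config, arch = arch, params = p),
            class = "odss_encoder")
}

#' @export
print.odss_encoder <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("Weight-sharing residual encoder (", x$config$backbone_depth,
      " backbone)\n", sep = "")
  cat("  feature dim:", x$config$feature_dim,
      " embedding dim:", x$config$projection_dim, "\n")
  cat("  parameters:", format(n_par, big.mark = ","), "\n")
  invisible(x)
}

# Full forward pass on a batch tensor (H, W, 1, B). Returns the pooled
# feature (feature_dim x B), the unit-norm embedding (projection_dim x B),
# and, when requested, the caches the backward pass needs.
encoder_fw <- function(enc, x, keep_cache = FALSE) {
  p <- enc$params
  cc <- if (keep_cache) list() else NULL
  st <- conv_fw(x, p[["stem.W"]], p[["stem.b"]], 3L)
  r <- relu_fw(st$out)
  pl <- pool_fw(r$out)
  if (keep_cache) cc$stem <- list(conv = st$cache, relu = r$cache,
                                  pool = pl$cache)
  h <- pl$out
  for (si in seq_along(enc$arch$stages)) {
    stg <- enc$arch$stages[[si]]
    for (bi in seq_len(stg$blocks)) {
      pre <- sprintf("s%d.b%d", si, bi)
      c1 <- conv_fw(h, p[[paste0(pre, ".conv1.W")]],
                    p[[paste0(pre, ".conv1.b")]], 3L)
      r1 <- relu_fw(c1$out)
      c2 <- conv_fw(r1$out, p[[paste0(pre, ".conv2.W")]],
                    p[[paste0(pre, ".conv2.b")]], 3L)
      if (!is.null(p[[paste0(pre, ".skip.W")]])) {
        sk <- conv_fw(h, p[[paste0(pre, ".skip.W")]],
                      p[[paste0(pre, ".skip.b")]], 1L)
        pre_sum <- c2$out + sk$out
        sk_cache <- sk$cache
      } else {
        pre_sum <- c2$out + h
        sk_cache <- NULL
      }
      r2 <- relu_fw(pre_sum)
      if (keep_cache) {
        cc[[pre]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                          skip = sk_cache, r2 = r2$cache)
      }
      h <- r2$out
    }
    pl <- pool_fw(h)
    if (keep_cache) cc[[sprintf("pool%d", si)]] <- pl$cache
    h <- pl$out
  }
  hd <- conv_fw(h, p[["head.W"]], p[["head.b"]], 1L)
  rh <- relu_fw(hd$out)
  gp <- gap_fw(rh$out)
  feat <- gp$out                      # (feature_dim, B)
  if (keep_cache) cc$head <- list(conv = hd$cache, relu = rh$cache,
                                  gap = gp$cache)
  pr <- project_fw(enc, feat, keep_cache)
  if (keep_cache) cc$proj <- pr$cache
  list(feature = feat, embedding = pr$out, cache = cc)
}

project_fw <- function(enc, feat, keep_cache = FALSE) {
  p <- enc$params
  cache <- list(feat = feat)
  h <- feat
  if (enc$config$projection_layers == 2L) {
    v1 <- t(p[["proj1.W"]]) %*% h + p[["proj1.b"]]
    r1 <- relu_fw(v1)
    cache$r1 <- r1$cache
    cache$h1_in <- h
    h <- r1$out
    cache$h1 <- h
  }
  v <- t(p[["proj.W"]]) %*% h
  if (!is.null(p[["proj.b"]])) v <- v + p[["proj.b"]]
  nz <- l2norm_fw(v)
  cache$l2 <- nz$cache
  list(out = nz$out, cache = if (keep_cache) cache else NULL)
}

# Backward from d(loss)/d(embedding) to parameter gradients.
encoder_bw <- function(enc, cc, dZ) {
  p <- enc$params
  g <- list()
  # projection head
  dv <- l2norm_bw(dZ, cc$proj$l2)
  h_last <- if (enc$config$projection_layers == 2L) cc$proj$h1 else
    cc$proj$feat
  g[["proj.W"]] <- h_last %*% t(dv)
  if (!is.null(p[["proj.b"]])) g[["proj.b"]] <- rowSums(dv)
  dh <- p[["proj.W"]] %*% dv
  if (enc$config$projection_layers == 2L) {
    dv1 <- relu_bw(dh, cc$proj$r1)
    g[["proj1.W"]] <- cc$proj$h1_in %*% t(dv1)
    g[["proj1.b"]] <- rowSums(dv1)
    dh <- p[["proj1.W"]] %*% dv1
  }
  dfeat <- dh
  # head conv + gap
  dgap <- gap_bw(dfeat, cc$head$gap)
  drh <- relu_bw(dgap, cc$head$relu)
  bw <- conv_bw(drh, p[["head.W"]], 1L, cc$head$conv)
  g[["head.W"]] <- bw$dW; g[["head.b"]] <- bw$db
  dh <- bw$dx
  # stages, in reverse
  for (si in rev(seq_along(enc$arch$stages))) {
    stg <- enc$arch$stages[[si]]
    dh <- pool_bw(dh, cc[[sprintf("pool%d", si)]])
    for (bi in rev(seq_len(stg$blocks))) {
      pre <- sprintf("s%d.b%d", si, bi)
      bc <- cc[[pre]]
      dsum <- relu_bw(dh, bc$r2)
      bw2 <- conv_bw(dsum, p[[paste0(pre, ".conv2.W")]], 3L, bc$c2)
      g[[paste0(pre, ".conv2.W")]] <- bw2$dW
      g[[paste0(pre, ".conv2.b")]] <- bw2$db
      dr1 <- relu_bw(bw2$dx, bc$r1)
      bw1 <- conv_bw(dr1, p[[paste0(pre, ".conv1.W")]], 3L, bc$c1)
      g[[paste0(pre, ".conv1.W")]] <- bw1$dW
      g[[paste0(pre, ".conv1.b")]] <- bw1$db
      if (!is.null(bc$skip)) {
        bws <- conv_bw(dsum, p[[paste0(pre, ".skip.W")]], 1L, bc$skip)
        g[[paste0(pre, ".skip.W")]] <- bws$dW
        g[[paste0(pre, ".skip.b")]] <- bws$db
        dh <- bw1$dx + bws$dx
      } else {
        dh <- bw1$dx + dsum
      }
    }
  }
  # stem
  dpool <- pool_bw(dh, cc$stem$pool)
  dr <- relu_bw(dpool, cc$stem$relu)
  bws <- conv_bw(dr, p[["stem.W"]], 3L, cc$stem$conv)
  g[["stem.W"]] <- bws$dW; g[["stem.b"]] <- bws$db
  g
}

images_to_tensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(unlist(images, use.names = FALSE), c(d[1], d[2], length(images)))
  dim(x) <- c(d[1], d[2], 1L, length(images))
  x
}

#' Project pooled feature vectors onto the embedding hypersphere
#'
#' Applies the encoder's projection head (a single linear map by default)
#' followed by L2 normalization. A zero vector after projection is an
#' error, never silently returned.
#'
#' @param encoder an `odss_encoder`.
#' @param feature numeric vector of length `feature_dim`, or a matrix with
#'   one feature per column.
#' @return unit-norm embedding(s), same orientation as the input.
#' @export
project <- function(encoder, feature) {
  stopifnot(inherits(encoder, "odss_encoder"))
  vec_in <- !is.matrix(feature)
  f <- if (vec_in) matrix(feature, ncol = 1L) else feature
  if (nrow(f) != encoder$config$feature_dim) {
    stop("feature has length ", nrow(f), ", expected ",
         encoder$config$feature_dim, call. = FALSE)
  }
  if (!all(is.finite(f))) stop("feature must be finite", call. = FALSE)
  z <- project_fw(encoder, f)$out
  if (vec_in) as.numeric(z) else z
}

#' Embed a collection of images
#'
#' Images pass through the single shared parameter set in inference mode:
#' no batch-coupled statistics exist anywhere in the network, so an image's
#' embedding is independent of its batch companions and of batch order.
#'
#' @param encoder an `odss_encoder`.
#' @param images an `odss_dataset`, or a list of `[0, 1]` matrices.
#' @param chunk_size internal forward-pass batch size (no effect on values).
#' @return matrix of embeddings, one column per image (`projection_dim` x n).
#' @export
embed_batch <- function(encoder, images, chunk_size = 64L) {
  stopifnot(inherits(encoder, "odss_encoder"))
  if (inherits(images, "odss_dataset")) images <- images$images
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0L) stop("no images to embed", call. = FALSE)
  n <- length(images)
  out <- matrix(0, encoder$config$projection_dim, n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    x <- images_to_tensor(images[idx])
    out[, idx] <- encoder_fw(encoder, x)$embedding
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' The configuration travels inside the checkpoint, so a reloaded encoder
#' reproduces embeddings exactly.
#'
#' @param encoder an `odss_encoder`.
#' @param path checkpoint file path.
#' @return `save_encoder`: invisibly, `path`; `load_encoder`: the encoder.
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "odss_encoder"))
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  enc <- readRDS(path)
  if (!inherits(enc, "odss_encoder")) {
    stop(path, " is not an encoder checkpoint", call. = FALSE)
  }
  enc
}
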