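# Supervised contrastive loss and the twin-channel training loop.
#
# For anchor i with positives P(i) = { j != i : y_j = y_i },
#
#   L_i = -(1/|P(i)|) * sum_{j in P(i)} log[ exp(z_i.z_j / tau) /
#                                            sum_{k != i} exp(z_i.z_k / tau) ]
#
# and the batch loss is the sum of L_i over all 2N anchors (reported
# alongside its mean). Positives are same-label pairs: the printed loss in
# some write-ups carries an inverted label indicator, which contradicts the
# definition of supervised contrastive learning and is treated here as a
# typo. Computed with a max-shifted log-sum-exp for stability.

#' Supervised contrastive loss
#'
#' @param embeddings matrix with one unit-norm embedding per row (2N x d
#'   for a duplicated batch of N images, but any n >= 2 works).
#' @param labels length-n vector of class labels.
#' @param temperature temperature tau > 0 (default 0.07).
#' @param strict if `TRUE` (default), an anchor with no positive is an
#'   error; if `FALSE`, such anchors are excluded with a warning (the
#'   training-loop behavior).
#' @param grad if `TRUE`, also return the gradient of the mean per-anchor
#'   loss with respect to the embeddings.
#' @return an object of class `supcon_loss`: `per_anchor` (NA for excluded
#'   anchors), `sum`, `mean`, `n_anchors`, `excluded`, and optionally `grad`.
#' @export
supcon_loss <- function(embeddings, labels, temperature = 0.07,
                        strict = TRUE, grad = FALSE) {
  if (!is.matrix(embeddings)) {
    stop("embeddings must be a matrix with one embedding per row",
         call. = FALSE)
  }
  n <- nrow(embeddings)
  if (n < 2L) stop("need at least 2 embeddings", call. = FALSE)
  if (length(labels) != n) {
    stop("labels length ", length(labels), " != ", n, " embeddings",
         call. = FALSE)
  }
  stopifnot_scalar_number(temperature, "temperature")
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(abs(nrm - 1) > 1e-4)) {
    stop("embeddings must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ")", call. = FALSE)
  }
  labels <- as.character(labels)

  S <- tcrossprod(embeddings) / temperature
  pos <- outer(labels, labels, "==")
  diag(pos) <- FALSE
  npos <- rowSums(pos)
  valid <- npos > 0L
  if (!all(valid)) {
    msg <- paste0(sum(!valid), " anchor(s) have no positive in the batch")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; excluded from the loss", call. = FALSE)
  }
  # log-sum-exp over k != i, max-shifted
  Sx <- S
  diag(Sx) <- -Inf
  mx <- apply(Sx, 1L, max)
  lse <- mx + log(rowSums(exp(Sx - mx)))
  per <- rep(NA_real_, n)
  per[valid] <- lse[valid] -
    (rowSums(S * pos)[valid] / npos[valid])
  n_valid <- sum(valid)
  res <- structure(list(
    per_anchor = per,
    sum = sum(per[valid]),
    mean = sum(per[valid]) / n_valid,
    n_anchors = n_valid,
    excluded = which(!valid),
    temperature = temperature
  ), class = "supcon_loss")
  if (grad) {
    P <- exp(Sx - lse)            # row-softmax over k != i; diag is 0
    G <- matrix(0, n, n)
    G[valid, ] <- P[valid, ] - pos[valid, ] / npos[valid]
    G <- G / n_valid
    res$grad <- (G + t(G)) %*% embeddings / temperature
  }
  res
}

#' @export
print.supcon_loss <- function(x, ...) {
  cat("Supervised contrastive loss: sum", format(x$sum, digits = 6),
      "| mean per anchor", format(x$mean, digits = 6),
      "| anchors", x$n_anchors, "\n")
  if (length(x$excluded)) {
    cat("  excluded anchors (no positive):", length(x$excluded), "\n")
  }
  invisible(x)
}

#' Training configuration
#'
#' @param batch_size images N drawn per step; the twin channels see the
#'   2N-sample duplicated batch.
#' @param temperature SupCon temperature tau (default 0.07).
#' @param epochs full passes over the training split.
#' @param learning_rate Adam step size.
#' @param optimizer currently `"adam"`.
#' @param augmentation `"none"` (the second channel receives exact copies)
#'   or `"light"` (the copy is horizontally flipped with probability 1/2).
#' @param seed integer seed controlling batch order and augmentation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, temperature = 0.07, epochs = 8L,
                         learning_rate = 1e-3, optimizer = "adam",
                         augmentation = c("none", "light"), seed = 1L) {
  augmentation <- match.arg(augmentation)
  optimizer <- match.arg(optimizer, "adam")
  stopifnot_scalar_number(batch_size, "batch_size", TRUE)
  stopifnot_scalar_number(temperature, "temperature", TRUE)
  stopifnot_scalar_number(epochs, "epochs")
  if (epochs < 0 || epochs != round(epochs)) {
    stop("epochs must be a nonnegative integer", call. = FALSE)
  }
  stopifnot_scalar_number(learning_rate, "learning_rate", TRUE)
  structure(list(batch_size = as.integer(batch_size),
                 temperature = temperature, epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

flip_h <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Train an encoder with the supervised contrastive strategy
#'
#' Each step samples N training images, duplicates the batch into the two
#' channels (2N samples; with `augmentation = "light"` the copies may be
#' horizontally flipped), embeds all 2N through the single shared parameter
#' set, applies [supcon_loss()], and takes one Adam step on the mean
#' per-anchor loss. Fully reproducible for a fixed seed.
#'
#' @param encoder an `odss_encoder` (its weights are the starting point).
#' @param data an `odss_dataset`; only the training split is used when a
#'   split is present.
#' @param config a [train_config()].
#' @return a list: `encoder` (trained), `history` (data.frame with one row
#'   per epoch: `epoch`, `loss_mean`, `loss_sum`).
#' @export
train_encoder <- function(encoder, data, config = train_config()) {
  stopifnot(inherits(encoder, "odss_encoder"), inherits(data, "odss_dataset"),
            inherits(config, "train_config"))
  if (!is.null(data$meta$split)) data <- dataset_split(data, "train")
  labels <- as.character(data$meta$stage)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain at least 2 stages", call. = FALSE)
  }
  n <- length(data$images)
  if (config$epochs == 0L) {
    return(list(encoder = encoder,
                history = data.frame(epoch = integer(), loss_mean = numeric(),
                                     loss_sum = numeric())))
  }
  N <- min(config$batch_size, n)
  params <- encoder$params
  state <- list(t = 0L,
                m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  history <- data.frame(epoch = seq_len(config$epochs),
                        loss_mean = NA_real_, loss_sum = NA_real_)
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_mean <- ep_sum <- 0
      n_steps <- 0L
      for (start in seq(1L, n - 1L, by = N)) {
        idx <- perm[start:min(start + N - 1L, n)]
        if (length(idx) < 2L) next
        imgs <- data$images[idx]
        copies <- imgs
        if (config$augmentation == "light") {
          do_flip <- stats::runif(length(copies)) < 0.5
          copies[do_flip] <- lapply(copies[do_flip], flip_h)
        }
        x <- images_to_tensor(c(imgs, copies))
        y <- c(labels[idx], labels[idx])
        encoder$params <- params
        fw <- encoder_fw(encoder, x, keep_cache = TRUE)
        loss <- supcon_loss(t(fw$embedding), y,
                            temperature = config$temperature,
                            strict = FALSE, grad = TRUE)
        if (!is.finite(loss$mean)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               call. = FALSE)
        }
        grads <- encoder_bw(encoder, fw$cache, t(loss$grad))
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_mean <- ep_mean + loss$mean
        ep_sum <- ep_sum + loss$sum
        n_steps <- n_steps + 1L
      }
      history$loss_mean[ep] <- ep_mean / n_steps
      history$loss_sum[ep] <- ep_sum / n_steps
    }
  })
  encoder$params <- params
  list(encoder = encoder, history = history)
}
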