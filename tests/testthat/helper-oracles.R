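# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately written as explicit loops, independent of the
# vectorized implementations they check.

# Supervised contrastive loss by explicit double loop over anchors and
# positives; same-label positives, j != i.
supcon_loss_oracle <- function(Z, labels, tau) {
  n <- nrow(Z)
  per <- numeric(n)
  for (i in seq_len(n)) {
    pos <- setdiff(which(labels == labels[i]), i)
    stopifnot(length(pos) > 0)
    denom <- 0
    for (k in seq_len(n)) {
      if (k != i) denom <- denom + exp(sum(Z[i, ] * Z[k, ]) / tau)
    }
    li <- 0
    for (j in pos) {
      li <- li - log(exp(sum(Z[i, ] * Z[j, ]) / tau) / denom)
    }
    per[i] <- li / length(pos)
  }
  list(per_anchor = per, sum = sum(per), mean = mean(per))
}

# Exhaustive single-threshold scan: for every midpoint between sorted
# unique scores (padded beyond the ends), classify and track the best
# accuracy (ties toward higher sensitivity, then lower threshold).
binary_scan_oracle <- function(scores, is_pos, low_is_positive) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
             u[length(u)] + 1)
  best <- NULL
  for (thr in cands) {
    pred <- if (low_is_positive) scores <= thr else scores >= thr
    tp <- sum(pred & is_pos); fn <- sum(!pred & is_pos)
    tn <- sum(!pred & !is_pos); fp <- sum(pred & !is_pos)
    acc <- (tp + tn) / length(scores)
    sens <- tp / (tp + fn)
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(thr = thr, acc = acc, sens = sens,
                   spec = tn / (tn + fp))
    }
  }
  best
}

# Exhaustive two-cutpoint scan for the three-interval classifier:
# stage_order gives the stage of each interval from low to high score.
threeclass_scan_oracle <- function(scores, stages, stage_order) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
             u[length(u)] + 1)
  best <- list(acc = -1)
  for (a in seq_along(cands)) {
    for (b in seq_along(cands)) {
      if (b <= a) next
      pred <- ifelse(scores <= cands[a], stage_order[1],
                     ifelse(scores <= cands[b], stage_order[2],
                            stage_order[3]))
      acc <- mean(pred == as.character(stages))
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, cuts = c(cands[a], cands[b]))
      }
    }
  }
  best
}

random_unit_rows <- function(n, d) {
  Z <- matrix(rnorm(n * d), n, d)
  Z / sqrt(rowSums(Z^2))
}

# Duplicated-batch embeddings and labels: N images, 2N anchors, so every
# anchor has at least its own copy as a positive.
random_contrastive_batch <- function(N, d, n_classes = 3) {
  Z <- random_unit_rows(N, d)
  y <- sample(LETTERS[seq_len(n_classes)], N, replace = TRUE)
  list(Z = rbind(Z, Z), labels = c(y, y))
}

# Small phantom dataset for fast structural tests.
tiny_dataset <- function(seed = 1, n_sub = 8, ips = 2, size = 32) {
  generate_phantom_dataset(phantom_config(
    n_subjects_per_stage = n_sub, images_per_subject = ips,
    image_size = size, seed = seed))
}

tiny_encoder <- function(seed = 1, feature_dim = 64, projection_dim = 16) {
  build_encoder(encoder_config(feature_dim = feature_dim,
                               projection_dim = projection_dim, seed = seed))
}
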