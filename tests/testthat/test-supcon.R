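# Supervised contrastive loss: closed forms, oracle equivalence,
# invariances, gradients, and the training loop.

test_that("identical embeddings give per-anchor loss log(2N - 1)", {
  for (N in c(2, 4, 8)) {
    z <- l2_normalize(rnorm(16))
    Z <- matrix(z, 2 * N, 16, byrow = TRUE)
    y <- rep(c("A", "B"), N)
    l <- supcon_loss(Z, y, temperature = 0.07)
    expect_equal(l$per_anchor, rep(log(2 * N - 1), 2 * N), tolerance = 1e-6)
    expect_equal(l$sum, 2 * N * log(2 * N - 1), tolerance = 1e-6)
  }
})

test_that("vectorized loss equals the double-loop oracle", {
  set.seed(2024)
  # the spec example shape: 6 random unit vectors, labels AABBCC, tau 0.1
  Z <- random_unit_rows(6, 16)
  y <- c("A", "A", "B", "B", "C", "C")
  l <- supcon_loss(Z, y, temperature = 0.1)
  o <- supcon_loss_oracle(Z, y, 0.1)
  expect_equal(l$per_anchor, o$per_anchor, tolerance = 1e-6)
  expect_equal(l$sum, o$sum, tolerance = 1e-6)
  expect_equal(l$mean, o$mean, tolerance = 1e-6)

  for (rep in 1:25) {
    b <- random_contrastive_batch(sample(2:8, 1), sample(c(8, 32, 128), 1))
    tau <- runif(1, 0.05, 1)
    l <- supcon_loss(b$Z, b$labels, temperature = tau)
    o <- supcon_loss_oracle(b$Z, b$labels, tau)
    expect_equal(l$per_anchor, o$per_anchor, tolerance = 1e-6)
  }
})

test_that("loss is invariant to permuting the batch", {
  set.seed(5)
  b <- random_contrastive_batch(5, 24)
  l0 <- supcon_loss(b$Z, b$labels, temperature = 0.2)
  perm <- sample(nrow(b$Z))
  l1 <- supcon_loss(b$Z[perm, ], b$labels[perm], temperature = 0.2)
  expect_equal(l0$sum, l1$sum, tolerance = 1e-6)
  expect_equal(l0$per_anchor[perm], l1$per_anchor, tolerance = 1e-6)
})

test_that("tightening a positive pair never increases the loss", {
  # z1 = e1 and z2 rotates toward it in the (e1, e2) plane; the other pair
  # lives in the orthogonal (e3, e4) plane, so all other similarities are
  # pinned at zero while sim(z1, z2) = cos(theta) varies.
  d <- 8
  e <- diag(d)
  losses <- vapply(seq(pi / 2, 0.05, length.out = 10), function(theta) {
    Z <- rbind(e[1, ], cos(theta) * e[1, ] + sin(theta) * e[2, ],
               e[3, ], cos(0.7) * e[3, ] + sin(0.7) * e[4, ])
    supcon_loss(Z, c("A", "A", "B", "B"), temperature = 0.3)$sum
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
  # separable limit: aligned positives, orthogonal negatives, small tau
  Z <- rbind(e[1, ], e[1, ], e[2, ], e[2, ])
  expect_lt(supcon_loss(Z, c("A", "A", "B", "B"),
                        temperature = 0.01)$mean, 1e-10)
})

test_that("precondition violations are errors (or warnings when lenient)", {
  Z <- random_unit_rows(4, 8)
  expect_error(supcon_loss(Z, c("A", "A", "B", "B"), temperature = 0),
               "> 0")
  expect_error(supcon_loss(Z, c("A", "A", "B", "C")), "no positive")
  expect_warning(l <- supcon_loss(Z, c("A", "A", "B", "C"), strict = FALSE),
                 "excluded")
  expect_equal(l$n_anchors, 2L)
  expect_error(supcon_loss(2 * Z, c("A", "A", "B", "B")), "unit-norm")
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(77)
  b <- random_contrastive_batch(3, 10)
  tau <- 0.25
  l <- supcon_loss(b$Z, b$labels, temperature = tau, grad = TRUE)
  # project the gradient onto the sphere's tangent at each row, because
  # finite-difference steps must stay on the sphere where the loss lives;
  # instead perturb freely and normalize inside the objective
  f <- function(Zflat) {
    Z <- matrix(Zflat, nrow(b$Z), ncol(b$Z))
    supcon_loss(Z / sqrt(rowSums(Z^2)), b$labels, temperature = tau)$mean
  }
  eps <- 1e-6
  for (trial in 1:8) {
    i <- sample(length(b$Z), 1)
    zp <- as.numeric(b$Z); zm <- as.numeric(b$Z)
    zp[i] <- zp[i] + eps; zm[i] <- zm[i] - eps
    num <- (f(zp) - f(zm)) / (2 * eps)
    # analytic grad is for unnormalized input = on-sphere point, so chain
    # through the normalization jacobian at norm 1
    Z <- b$Z
    row <- (i - 1) %% nrow(Z) + 1
    g_row <- l$grad[row, ]
    z_row <- Z[row, ]
    g_chain <- g_row - z_row * sum(z_row * g_row)
    col <- (i - 1) %/% nrow(Z) + 1
    expect_equal(num, g_chain[col], tolerance = 1e-4)
  }
})

test_that("encoder backprop matches finite differences end to end", {
  set.seed(99)
  cfg <- encoder_config(feature_dim = 12, projection_dim = 6, seed = 3)
  enc <- build_encoder(cfg)
  imgs <- lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32))
  labels <- c("A", "A", "B", "B")
  x <- odssmri:::images_to_tensor(imgs)
  fw <- odssmri:::encoder_fw(enc, x, keep_cache = TRUE)
  l <- supcon_loss(t(fw$embedding), labels, temperature = 0.2, grad = TRUE)
  grads <- odssmri:::encoder_bw(enc, fw$cache, t(l$grad))
  loss_of <- function(params) {
    enc$params <- params
    f <- odssmri:::encoder_fw(enc, x)
    supcon_loss(t(f$embedding), labels, temperature = 0.2)$mean
  }
  eps <- 1e-5
  for (nm in c("stem.W", "s1.b1.conv1.W", "s2.b1.conv2.W", "s2.b1.skip.W",
               "head.W", "proj.W")) {
    i <- sample(length(enc$params[[nm]]), 1)
    pp <- enc$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- enc$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})

test_that("training decreases the loss, is seeded, and 0 epochs is a no-op", {
  data <- tiny_dataset(seed = 21)
  enc <- tiny_encoder(seed = 22)
  cfg <- train_config(batch_size = 8, epochs = 4, seed = 23)
  fit <- train_encoder(enc, data, cfg)
  expect_equal(nrow(fit$history), 4L)
  expect_true(all(is.finite(fit$history$loss_mean)))
  expect_lt(fit$history$loss_mean[4], fit$history$loss_mean[1])

  fit2 <- train_encoder(enc, data, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$encoder$params, fit2$encoder$params)

  noop <- train_encoder(enc, data, train_config(epochs = 0))
  expect_identical(noop$encoder$params, enc$params)
  expect_equal(nrow(noop$history), 0L)
})

test_that("light augmentation trains and stays reproducible", {
  data <- tiny_dataset(seed = 31)
  enc <- tiny_encoder(seed = 32)
  cfg <- train_config(batch_size = 8, epochs = 1, seed = 33,
                      augmentation = "light")
  f1 <- train_encoder(enc, data, cfg)
  f2 <- train_encoder(enc, data, cfg)
  expect_identical(f1$history, f2$history)
})
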