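# Evaluation battery: correlations, t-tests, threshold classifiers,
# dispersion, Pareto bins.

test_that("correlation with stage: closed cases and midrank ties", {
  r <- correlation_with_stage(c(3, 2, 1), c("NC", "MCI", "AD"))
  expect_equal(r$pearson, -1)
  expect_equal(r$spearman, -1)
  expect_equal(r$pearson_pct, 100)

  r2 <- correlation_with_stage(c(0, 1, 1, 2), c("NC", "MCI", "MCI", "AD"))
  expect_equal(r2$pearson, 1)
  expect_equal(r2$spearman, 1)

  # ties: spearman must equal rank-then-Pearson with midranks
  sc <- c(1, 2, 2, 3)
  st <- c("NC", "MCI", "MCI", "AD")
  code <- c(0, 1, 1, 2)
  oracle <- stats::cor(rank(sc), rank(code), method = "pearson")
  expect_equal(correlation_with_stage(sc, st)$spearman, oracle,
               tolerance = 1e-12)

  expect_error(correlation_with_stage(c(1, 1, 1), st[1:3]), "constant")
  expect_error(correlation_with_stage(c(1, 2), c("NC", "AD")), "at least 3")
  expect_error(correlation_with_stage(c(1, 2, 3), c("NC", "NC", "NC")),
               "distinct stages")
})

test_that("pairwise t-tests: null, extreme, and variant flag", {
  sc <- c(1, 2, 3, 1, 2, 3, 9, 9, 9)
  st <- c(rep("NC", 3), rep("MCI", 3), rep("AD", 3))
  p <- pairwise_ttests(sc, st, var_equal = TRUE)
  expect_named(p, c("NC/MCI", "MCI/AD", "NC/AD"))
  expect_equal(unname(p["NC/MCI"]), 1)        # identical groups, t = 0

  sc2 <- c(0, 0, 0, 1e-8, 10, 10, 10, 10 + 1e-8, 20, 20)
  st2 <- c(rep("NC", 4), rep("MCI", 4), rep("AD", 2))
  p2 <- pairwise_ttests(sc2, st2)
  expect_lt(unname(p2["NC/MCI"]), 1e-6)

  # Welch and pooled differ under unequal variances
  sc3 <- c(rnorm(10, 0, 0.1), rnorm(10, 1, 3), rnorm(10, 2, 1))
  st3 <- rep(c("NC", "MCI", "AD"), each = 10)
  expect_false(isTRUE(all.equal(pairwise_ttests(sc3, st3),
                                pairwise_ttests(sc3, st3, var_equal = TRUE))))

  expect_error(pairwise_ttests(c(1, 2, 3, 4), c("NC", "NC", "MCI", "AD")),
               "fewer than 2")
})

test_that("binary threshold metrics: separable case and arithmetic", {
  sc <- c(10, 9, 8, 7, 3, 2, 1)
  st <- c(rep("NC", 4), rep("AD", 3))
  m <- binary_threshold_metrics(sc, st, c("NC", "AD"))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$direction, "low_is_positive")

  # rates always recompute from the emitted confusion matrix
  cm <- m$confusion
  expect_equal(m$sensitivity, cm[1, 1] / sum(cm[1, ]))
  expect_equal(m$specificity, cm[2, 2] / sum(cm[2, ]))
  expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("binary threshold search equals the exhaustive-scan oracle", {
  set.seed(60)
  for (rep in 1:10) {
    n <- sample(30:200, 1)
    st <- sample(c("NC", "AD"), n, replace = TRUE)
    while (length(unique(st)) < 2) st <- sample(c("NC", "AD"), n, TRUE)
    sc <- rnorm(n, mean = ifelse(st == "AD", -0.8, 0.8))
    m <- binary_threshold_metrics(sc, st, c("NC", "AD"))
    o <- binary_scan_oracle(sc, st == "AD",
                            m$direction == "low_is_positive")
    expect_equal(m$accuracy, o$acc, tolerance = 1e-12)
    expect_equal(m$sensitivity, o$sens, tolerance = 1e-12)
    expect_equal(m$specificity, o$spec, tolerance = 1e-12)
  }
})

test_that("three-class metrics: separable case, consistency, oracle", {
  sc <- c(10, 9, 8, 6, 5, 4, 2, 1, 0)
  st <- rep(c("NC", "MCI", "AD"), each = 3)
  m <- threeclass_threshold_metrics(sc, st)
  expect_true(all(m$per_stage$sensitivity == 1))
  expect_true(all(m$per_stage$specificity == 1))
  expect_equal(m$accuracy, 1)
  expect_equal(m$stage_order, c("AD", "MCI", "NC"))

  set.seed(61)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    st <- sample(c("NC", "MCI", "AD"), n, replace = TRUE)
    while (length(unique(st)) < 3) st <- sample(c("NC", "MCI", "AD"), n, TRUE)
    mu <- c(NC = 2, MCI = 0, AD = -2)
    sc <- rnorm(n, mean = mu[st], sd = 1.2)
    m <- threeclass_threshold_metrics(sc, st)
    o <- threeclass_scan_oracle(sc, st, m$stage_order)
    expect_equal(m$accuracy, o$acc, tolerance = 1e-12)
    # per-stage rates recompute exactly from the emitted confusion matrix
    cm <- m$confusion
    for (k in seq_len(nrow(m$per_stage))) {
      stg <- m$per_stage$stage[k]
      tp <- cm[stg, stg]
      fn <- sum(cm[stg, ]) - tp
      fp <- sum(cm[, stg]) - tp
      tn <- n - tp - fn - fp
      expect_equal(m$per_stage$sensitivity[k], tp / (tp + fn))
      expect_equal(m$per_stage$specificity[k], tn / (tn + fp))
      expect_equal(m$per_stage$accuracy[k], (tp + tn) / n)
    }
  }
  expect_error(threeclass_threshold_metrics(c(1, 2), c("NC", "AD")),
               "three stages")
})

test_that("dispersion of normalized scores matches hand-computed values", {
  d <- dispersion_table(c(0, 0.5, 1))
  expect_equal(d$quartile_deviation, 0.25)   # (0.75 - 0.25) / 2, type-7

  d2 <- dispersion_table(c(1, 1, 2, 3))
  expect_equal(d2$variation_ratio, 0.5)      # 1 - 2/4

  d3 <- dispersion_table(rep(4, 5))
  expect_equal(unlist(d3), c(variance = 0, std = 0, quartile_deviation = 0,
                             variation_ratio = 0))

  # fixed 10-element vector, hand-evaluated population forms
  x <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10)
  z <- x / 10
  mu <- mean(z)
  expect_equal(dispersion_table(x)$variance, mean((z - mu)^2))
  expect_equal(dispersion_table(x)$std, sqrt(mean((z - mu)^2)))
  q <- unname(quantile(z, c(0.25, 0.75)))
  expect_equal(dispersion_table(x)$quartile_deviation, (q[2] - q[1]) / 2)
  expect_equal(dispersion_table(x)$variation_ratio, 1 - 1 / 10)
  expect_error(dispersion_table(3), "at least 2")
})

test_that("pareto bins: uniform fill, point mass, conservation", {
  p <- pareto_bins(seq(0.5, 9.5, by = 1), n_bins = 10)
  expect_equal(p$frequencies, rep(1L, 10))
  expect_equal(p$cumulative_percent, seq(10, 100, by = 10))

  p2 <- pareto_bins(rep(3, 7), n_bins = 5)
  expect_equal(sum(p2$frequencies), 7L)
  expect_equal(max(p2$cumulative_percent), 100)
  expect_equal(sum(p2$frequencies > 0), 1L)

  set.seed(62)
  x <- rnorm(137)
  p3 <- pareto_bins(x, n_bins = 12)
  expect_equal(sum(p3$frequencies), 137L)
  expect_true(all(diff(p3$cumulative_percent) >= 0))
  expect_identical(p3$cumulative_percent[12], 100)
  expect_length(p3$bin_edges, 13L)
})

test_that("evaluate_scores assembles a coherent report", {
  set.seed(63)
  st <- rep(c("NC", "MCI", "AD"), each = 40)
  sc <- rnorm(120, mean = c(NC = 90, MCI = 40, AD = -30)[st], sd = 18)
  rep_ <- evaluate_scores(data.frame(score = sc, stage = st))
  expect_s3_class(rep_, "odss_eval")
  expect_lt(rep_$correlation$pearson, 0)
  expect_true(all(unlist(rep_$ttests) <= 1 & unlist(rep_$ttests) > 0))
  expect_named(rep_$binary, c("NC/MCI", "MCI/AD", "NC/AD"))
  expect_output(print(rep_), "Pearson")
  p <- tempfile(fileext = ".json")
  write_eval_report(rep_, p)
  parsed <- jsonlite::fromJSON(p)
  expect_equal(parsed$correlation$pearson, rep_$correlation$pearson,
               tolerance = 1e-9)
})
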