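# Cosine scoring against the healthy-baseline panel.

test_that("cosine score identities", {
  e1 <- c(1, rep(0, 7)); e2 <- c(0, 1, rep(0, 6))
  expect_equal(cosine_score(e1, e1), 100, tolerance = 1e-6)
  expect_equal(cosine_score(e1, e2), 0, tolerance = 1e-6)
  expect_equal(cosine_score(e1, -e1), -100, tolerance = 1e-6)
  expect_error(cosine_score(rep(0, 8), e1), "zero-norm")
  expect_error(cosine_score(2 * e1, e1), "unit-norm")
  set.seed(1)
  z1 <- l2_normalize(rnorm(128)); z2 <- l2_normalize(rnorm(128))
  s <- cosine_score(z1, z2)
  expect_gte(s, -100); expect_lte(s, 100)
})

test_that("baseline panel draws five distinct NC training subjects, seeded", {
  data <- tiny_dataset(seed = 41, n_sub = 10)
  enc <- tiny_encoder(seed = 42)
  p1 <- build_baseline_panel(data, enc, seed = 7)
  expect_s3_class(p1, "baseline_panel")
  expect_length(p1$subject_ids, 5L)
  expect_length(unique(p1$subject_ids), 5L)
  train_nc <- unique(data$meta$subject_id[
    data$meta$split == "train" & data$meta$stage == "NC"])
  expect_true(all(p1$subject_ids %in% train_nc))
  p2 <- build_baseline_panel(data, enc, seed = 7)
  expect_identical(p1$subject_ids, p2$subject_ids)
  expect_identical(p1$embeddings, p2$embeddings)
})

test_that("exactly five NC training subjects forces the whole panel", {
  data <- tiny_dataset(seed = 43, n_sub = 12)
  train_nc <- unique(data$meta$subject_id[
    data$meta$split == "train" & data$meta$stage == "NC"])
  keep_nc <- train_nc[1:5]
  drop <- data$meta$stage == "NC" & data$meta$split == "train" &
    !data$meta$subject_id %in% keep_nc
  sub <- odss_dataset(data$images[!drop], data$meta[!drop, ])
  enc <- tiny_encoder(seed = 44)
  panel <- build_baseline_panel(sub, enc, seed = 3)
  expect_setequal(panel$subject_ids, keep_nc)

  # fewer than five is an error naming the count
  drop2 <- sub$meta$stage == "NC" & sub$meta$split == "train" &
    sub$meta$subject_id %in% keep_nc[1:2]
  sub2 <- odss_dataset(sub$images[!drop2], sub$meta[!drop2, ])
  expect_error(build_baseline_panel(sub2, enc), "found 3")
})

test_that("score is the panel mean and is panel-order invariant", {
  data <- tiny_dataset(seed = 45)
  enc <- tiny_encoder(seed = 46)
  panel <- build_baseline_panel(data, enc, seed = 1)
  img <- data$images[[which(data$meta$split == "test")[1]]]
  rec <- score_image(img, enc, panel)
  per <- as.numeric(rec[paste0("per_baseline_", 1:5)])
  expect_equal(rec$score, mean(per), tolerance = 1e-9)
  expect_true(all(per >= -100 - 1e-9 & per <= 100 + 1e-9))
  shuffled <- panel
  shuffled$embeddings <- panel$embeddings[, c(3, 5, 1, 4, 2)]
  expect_equal(score_image(img, enc, shuffled)$score, rec$score,
               tolerance = 1e-9)
})

test_that("a test image identical to every baseline image scores 100", {
  cfg <- phantom_config(
    n_subjects_per_stage = 6, images_per_subject = 1, image_size = 32,
    ventricle_scale_by_stage = list(NC = c(0, 0), MCI = c(0.4, 0.5),
                                    AD = c(0.8, 0.9)),
    noise_sd = 0, subject_effect_sd = 0, seed = 8)
  data <- generate_phantom_dataset(cfg)  # all NC images are pixel-identical
  data$meta$split <- "train"
  data <- odss_dataset(data$images, data$meta)
  enc <- tiny_encoder(seed = 47)
  panel <- build_baseline_panel(data, enc, seed = 2)
  nc_img <- data$images[[which(data$meta$stage == "NC")[1]]]
  expect_equal(score_image(nc_img, enc, panel)$score, 100, tolerance = 1e-6)
})

test_that("score_dataset: cardinality, determinism, CSV round trip", {
  data <- tiny_dataset(seed = 48)
  enc <- tiny_encoder(seed = 49)
  panel <- build_baseline_panel(data, enc, seed = 5)
  test <- dataset_split(data, "test")
  s1 <- score_dataset(test, enc, panel)
  expect_equal(nrow(s1), length(test$images))
  s2 <- score_dataset(test, enc, panel)
  expect_identical(s1, s2)
  p <- tempfile(fileext = ".csv")
  write_scores(s1, p)
  s3 <- read_scores(p)
  expect_equal(s3$score, s1$score, tolerance = 1e-9)
  expect_equal(as.character(s3$stage), as.character(s1$stage))
  expect_error(score_dataset(list(), enc, panel), "no images")

  # panel built with a different checkpoint is rejected
  enc2 <- tiny_encoder(seed = 50)
  expect_error(score_dataset(test, enc2, panel), "different encoder")
})

test_that("per-subject aggregation averages a subject's image scores", {
  data <- tiny_dataset(seed = 51, n_sub = 10, ips = 3)
  enc <- tiny_encoder(seed = 52)
  panel <- build_baseline_panel(data, enc, seed = 1)
  s <- score_dataset(dataset_split(data, "test"), enc, panel,
                     per_subject = TRUE)
  agg <- attr(s, "subject_scores")
  expect_false(is.null(agg))
  one <- agg$subject_id[1]
  expect_equal(agg$score[agg$subject_id == one],
               mean(s$score[s$subject_id == one]), tolerance = 1e-12)
})
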