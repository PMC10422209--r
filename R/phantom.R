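# Synthetic atrophy-phantom generator.
#
# Real cohort data for this kind of scoring model are access-controlled, so
# the package ships a generator of 2D "brain" phantoms whose morphology
# tracks a latent severity s in [0, 1]: an elliptical brain with a bright
# cortical band that thins as s grows, and a central dark ventricle system
# (two mirrored lobes) whose area grows monotonically with s -- the
# structural-MRI signature of progressive atrophy the scoring framework
# assumes.

#' Configuration for the atrophy-phantom generator
#'
#' @param n_subjects_per_stage subjects simulated per stage (NC, MCI, AD).
#' @param images_per_subject repeat scans per subject; repeats differ only
#'   by the additive noise field.
#' @param image_size pixels per side of the square slice (>= 32).
#' @param ventricle_scale_by_stage named list mapping each stage to the
#'   `[lo, hi]` interval its subjects' latent severity is drawn from.
#'   Intervals must be disjoint and ordered NC < MCI < AD; the default gaps
#'   make the stages separable by construction.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (intensity units; pixels are clipped back to `[0, 1]`).
#' @param subject_effect_sd standard deviation of the per-subject random
#'   offset added to the latent severity (then clipped to `[0, 1]`).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects_per_stage = 40L,
                           images_per_subject = 3L,
                           image_size = 64L,
                           ventricle_scale_by_stage = list(
                             NC = c(0.00, 0.15),
                             MCI = c(0.35, 0.55),
                             AD = c(0.75, 1.00)
                           ),
                           noise_sd = 0.03,
                           subject_effect_sd = 0.05,
                           seed = 1L) {
  stopifnot_scalar_number(n_subjects_per_stage, "n_subjects_per_stage", TRUE)
  stopifnot_scalar_number(images_per_subject, "images_per_subject", TRUE)
  if (n_subjects_per_stage != round(n_subjects_per_stage) ||
      images_per_subject != round(images_per_subject)) {
    stop("subject and image counts must be positive integers", call. = FALSE)
  }
  stopifnot_scalar_number(image_size, "image_size", TRUE)
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  stopifnot_scalar_number(subject_effect_sd, "subject_effect_sd")
  if (noise_sd < 0 || subject_effect_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  iv <- ventricle_scale_by_stage
  if (!all(STAGE_LEVELS %in% names(iv))) {
    stop("ventricle_scale_by_stage needs entries NC, MCI, AD", call. = FALSE)
  }
  for (st in STAGE_LEVELS) {
    v <- iv[[st]]
    if (length(v) != 2L || v[1] > v[2] || v[1] < 0 || v[2] > 1) {
      stop("stage interval for ", st, " must be [lo, hi] within [0, 1]",
           call. = FALSE)
    }
  }
  # disjoint and ordered NC < MCI < AD
  if (!(iv$NC[2] < iv$MCI[1] && iv$MCI[2] < iv$AD[1])) {
    stop("stage severity intervals must be disjoint and ordered NC < MCI < AD",
         call. = FALSE)
  }
  structure(list(
    n_subjects_per_stage = as.integer(n_subjects_per_stage),
    images_per_subject = as.integer(images_per_subject),
    image_size = as.integer(image_size),
    ventricle_scale_by_stage = iv[STAGE_LEVELS],
    noise_sd = noise_sd,
    subject_effect_sd = subject_effect_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Noise-free phantom slice for a given severity; pure function of (s, size).
# Geometry (in [-1, 1]^2 coordinates):
#   brain      ellipse semi-axes (0.80, 0.92), tissue intensity 0.55
#   cortex     band of relative radial width 0.18 * (1 - 0.5 s), intensity 0.90
#   ventricles two lobes centered at x = +/-0.14, semi-axes growing with s,
#              intensity 0.05
phantom_slice <- function(s, size = 64L) {
  stopifnot(s >= 0, s <= 1)
  ax <- seq(-1, 1, length.out = size)
  x <- matrix(ax, size, size)        # varies down rows
  y <- matrix(ax, size, size, byrow = TRUE)
  r2 <- (x / 0.80)^2 + (y / 0.92)^2
  img <- matrix(0, size, size)
  brain <- r2 <= 1
  img[brain] <- 0.55
  band <- 0.18 * (1 - 0.5 * s)
  cortex <- brain & (sqrt(r2) >= 1 - band)
  img[cortex] <- 0.90
  vx <- 0.08 + 0.30 * s
  vy <- 0.12 + 0.34 * s
  for (cx in c(-0.14, 0.14)) {
    lobe <- ((x - cx) / vx)^2 + (y / vy)^2 <= 1
    img[lobe & brain] <- 0.05
  }
  img
}

# Dark-region pixel count used by the monotonicity property: ventricle
# pixels are the only ones strictly between background (0) and tissue.
ventricle_pixels <- function(img, lo = 0.02, hi = 0.2) {
  sum(img > lo & img < hi)
}

#' Generate a synthetic atrophy-phantom dataset
#'
#' Each subject receives one latent severity `s`, drawn uniformly from its
#' stage's interval plus a clipped Gaussian subject effect; each of its
#' images is the deterministic phantom for that `s` plus i.i.d. additive
#' Gaussian noise truncated back to `[0, 1]`. Subjects are then split
#' 80/20 into train/test subject-wise.
#'
#' @param config a [phantom_config()].
#' @return an [odss_dataset()] with `severity_s` and `split` columns.
#' @export
generate_phantom_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n_sub <- config$n_subjects_per_stage
  n_img <- config$images_per_subject
  size <- config$image_size
  images <- vector("list", 3L * n_sub * n_img)
  meta <- data.frame(
    subject_id = character(length(images)),
    stage = character(length(images)),
    severity_s = numeric(length(images)),
    stringsAsFactors = FALSE
  )
  with_seed(derive_seed(config$seed, "phantom"), {
    k <- 0L
    for (st in STAGE_LEVELS) {
      iv <- config$ventricle_scale_by_stage[[st]]
      for (i in seq_len(n_sub)) {
        s <- stats::runif(1L, iv[1], iv[2]) +
          stats::rnorm(1L, 0, config$subject_effect_sd)
        s <- min(max(s, 0), 1)
        base <- phantom_slice(s, size)
        sid <- sprintf("%s%03d", st, i)
        for (j in seq_len(n_img)) {
          img <- base
          if (config$noise_sd > 0) {
            img <- img + matrix(stats::rnorm(size * size, 0, config$noise_sd),
                                size, size)
            img <- pmin(pmax(img, 0), 1)
          }
          k <- k + 1L
          images[[k]] <- img
          meta$subject_id[k] <- sid
          meta$stage[k] <- st
          meta$severity_s[k] <- s
        }
      }
    }
  })
  data <- odss_dataset(images, meta)
  split_by_subject(data, train_fraction = 0.8,
                   seed = derive_seed(config$seed, "split"))
}

#' Assign a subject-wise train/test split
#'
#' The split is by subject, never by image: every image of one subject lands
#' in the same partition. `round(train_fraction * n_subjects)` subjects are
#' assigned to the training split.
#'
#' @param data an [odss_dataset()].
#' @param train_fraction fraction of subjects assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed for the subject shuffle.
#' @return the dataset with its `split` column (re)set.
#' @export
split_by_subject <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(data, "odss_dataset"))
  stopifnot_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  subjects <- unique(data$meta$subject_id)
  if (length(subjects) < 2L) {
    stop("need at least 2 subjects to split (got ", length(subjects), ")",
         call. = FALSE)
  }
  n_train <- round(train_fraction * length(subjects))
  n_train <- min(max(n_train, 1L), length(subjects) - 1L)
  shuffled <- with_seed(seed, sample(subjects))
  train_ids <- shuffled[seq_len(n_train)]
  data$meta$split <- ifelse(data$meta$subject_id %in% train_ids,
                            "train", "test")
  odss_dataset(data$images, data$meta)
}
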