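# Neurological-function scoring: 100 x cosine similarity between a test
# embedding and each of five healthy-baseline embeddings, averaged over the
# panel. Healthy controls are assumed to share a consistent level of
# neurological function; averaging over five of them cancels what residual
# individual variation remains.

#' Build the healthy-baseline panel
#'
#' Samples one image from each of five distinct NC subjects of the training
#' split (baseline individuals are people, not images) and embeds them with
#' the supplied encoder.
#'
#' @param data an `odss_dataset` with split assignments.
#' @param encoder the trained `odss_encoder`.
#' @param seed integer seed for the subject/image draw.
#' @param n_baselines panel size; the method's default is 5.
#' @return an object of class `baseline_panel`: `subject_ids`, `image_idx`
#'   (indices into the training split), `embeddings` (d x n_baselines),
#'   `seed`, and a checkpoint fingerprint of the encoder weights.
#' @export
build_baseline_panel <- function(data, encoder, seed = 1L,
                                 n_baselines = 5L) {
  stopifnot(inherits(data, "odss_dataset"), inherits(encoder, "odss_encoder"))
  train <- if (is.null(data$meta$split)) data else dataset_split(data, "train")
  nc_idx <- which(train$meta$stage == "NC")
  nc_subjects <- unique(train$meta$subject_id[nc_idx])
  if (length(nc_subjects) < n_baselines) {
    stop("need at least ", n_baselines, " NC subjects in the training ",
         "split, found ", length(nc_subjects), call. = FALSE)
  }
  picks <- with_seed(derive_seed(seed, "panel"), {
    subjects <- sample(nc_subjects, n_baselines)
    vapply(subjects, function(sid) {
      cand <- nc_idx[train$meta$subject_id[nc_idx] == sid]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
  })
  emb <- embed_batch(encoder, train$images[picks])
  structure(list(
    subject_ids = train$meta$subject_id[picks],
    image_idx = unname(picks),
    embeddings = emb,
    seed = as.integer(seed),
    encoder_fingerprint = hash_object(lapply(encoder$params, function(p)
      round(sum(p) + sum(p^2), 10)))
  ), class = "baseline_panel")
}

#' @export
print.baseline_panel <- function(x, ...) {
  cat("Healthy baseline panel:", length(x$subject_ids), "NC subjects\n")
  cat("  subjects:", paste(x$subject_ids, collapse = ", "), "\n")
  cat("  selection seed:", x$seed, "\n")
  invisible(x)
}

#' Cosine similarity score between two embeddings
#'
#' `100 * (z1 . z2) / (||z1|| ||z2||)`; for unit vectors this is 100 times
#' the dot product. The value lies in `[-100, 100]` and is never clamped.
#'
#' @param z_test,z_base numeric vectors (unit norm within 1e-4).
#' @return a single number in `[-100, 100]`.
#' @export
cosine_score <- function(z_test, z_base) {
  n1 <- sqrt(sum(z_test^2))
  n2 <- sqrt(sum(z_base^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("cannot score a zero-norm embedding", call. = FALSE)
  }
  if (abs(n1 - 1) > 1e-4 || abs(n2 - 1) > 1e-4) {
    stop("embeddings must be unit-norm", call. = FALSE)
  }
  100 * sum(z_test * z_base) / (n1 * n2)
}

#' Score one image against the baseline panel
#'
#' @param image a `[0, 1]` matrix.
#' @param encoder the trained `odss_encoder` (must be the encoder the panel
#'   was built with).
#' @param panel a [build_baseline_panel()] result.
#' @return a one-row data.frame: `score` (mean of the five per-baseline
#'   scores) plus `per_baseline_1..k`.
#' @export
score_image <- function(image, encoder, panel) {
  stopifnot(inherits(encoder, "odss_encoder"),
            inherits(panel, "baseline_panel"))
  check_panel_encoder(panel, encoder)
  z <- as.numeric(embed_batch(encoder, list(image)))
  per <- apply(panel$embeddings, 2L, function(zb) cosine_score(z, zb))
  out <- as.data.frame(as.list(stats::setNames(
    per, paste0("per_baseline_", seq_along(per)))))
  out$score <- mean(per)
  out[, c("score", paste0("per_baseline_", seq_along(per)))]
}

check_panel_encoder <- function(panel, encoder) {
  fp <- hash_object(lapply(encoder$params, function(p)
    round(sum(p) + sum(p^2), 10)))
  if (!identical(fp, panel$encoder_fingerprint)) {
    stop("panel was built with a different encoder checkpoint; rebuild the ",
         "panel with this encoder", call. = FALSE)
  }
  invisible(TRUE)
}

#' Score every image of a dataset
#'
#' @param data an `odss_dataset` (typically the test split) or list of
#'   images.
#' @param encoder the trained `odss_encoder`.
#' @param panel a [build_baseline_panel()] result.
#' @param per_subject if `TRUE`, also return a per-subject aggregation
#'   (mean score across a subject's images) as attribute
#'   `"subject_scores"`.
#' @return data.frame with one row per image: `subject_id`, `stage`,
#'   `score`, `per_baseline_1..k` (metadata columns only when available).
#' @export
score_dataset <- function(data, encoder, panel, per_subject = FALSE) {
  stopifnot(inherits(encoder, "odss_encoder"),
            inherits(panel, "baseline_panel"))
  check_panel_encoder(panel, encoder)
  if (inherits(data, "odss_dataset")) {
    images <- data$images
    meta <- data$meta
  } else {
    images <- data
    meta <- NULL
  }
  if (length(images) == 0L) stop("no images to score", call. = FALSE)
  Z <- embed_batch(encoder, images)                   # d x n
  per <- 100 * crossprod(Z, panel$embeddings)         # n x k dot products
  colnames(per) <- paste0("per_baseline_", seq_len(ncol(per)))
  out <- data.frame(score = rowMeans(per))
  out <- cbind(out, as.data.frame(per))
  if (!is.null(meta)) {
    out <- cbind(meta[, intersect(c("subject_id", "stage", "severity_s",
                                    "split"), names(meta)), drop = FALSE],
                 out)
  }
  rownames(out) <- NULL
  if (per_subject && !is.null(meta)) {
    agg <- stats::aggregate(score ~ subject_id + stage, data = out, FUN = mean)
    attr(out, "subject_scores") <- agg
  }
  out
}

#' Write / read a scores table
#'
#' Plain CSV round trip; numeric columns survive to at least 1e-9.
#'
#' @param scores data.frame from [score_dataset()].
#' @param path CSV path.
#' @return `write_scores`: invisibly `path`; `read_scores`: the data.frame.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("stage" %in% names(out)) out$stage <- as_stage(out$stage)
  out
}
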