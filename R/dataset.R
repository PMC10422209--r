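# The labeled-slice dataset container shared by all modules.

#' Construct a labeled slice dataset
#'
#' A dataset couples a list of 2D grayscale slices (matrices with values in
#' `[0, 1]`) with a metadata table carrying subject id, ordinal disease stage
#' (NC < MCI < AD), an optional latent severity (phantoms only) and the
#' subject-wise train/test split assignment.
#'
#' @param images list of numeric matrices, pixel values in `[0, 1]`.
#' @param meta data.frame with one row per image and columns `subject_id`,
#'   `stage`, and optionally `severity_s` and `split`.
#' @return an object of class `odss_dataset`.
#' @export
odss_dataset <- function(images, meta) {
  stopifnot(is.list(images), is.data.frame(meta))
  if (length(images) != nrow(meta)) {
    stop("`images` and `meta` disagree: ", length(images), " images vs ",
         nrow(meta), " metadata rows", call. = FALSE)
  }
  if (!all(c("subject_id", "stage") %in% names(meta))) {
    stop("`meta` must contain columns subject_id and stage", call. = FALSE)
  }
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!is.matrix(img) || !is.numeric(img)) {
      stop("image ", i, " is not a numeric matrix", call. = FALSE)
    }
    if (!all(is.finite(img))) {
      stop("image ", i, " contains non-finite pixels", call. = FALSE)
    }
    if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
      stop("image ", i, " has pixels outside [0, 1]", call. = FALSE)
    }
  }
  meta$subject_id <- as.character(meta$subject_id)
  meta$stage <- as_stage(meta$stage)
  if (!is.null(meta$split)) {
    bad <- setdiff(unique(meta$split), c("train", "test"))
    if (length(bad)) {
      stop("split values must be 'train' or 'test'", call. = FALSE)
    }
    # subject-wise split: every image of a subject shares one assignment
    mix <- tapply(meta$split, meta$subject_id, function(x) length(unique(x)))
    if (any(mix > 1L)) {
      stop("subject(s) appear in both splits: ",
           paste(names(mix)[mix > 1L], collapse = ", "), call. = FALSE)
    }
  }
  rownames(meta) <- NULL
  structure(list(images = images, meta = meta), class = "odss_dataset")
}

#' @export
print.odss_dataset <- function(x, ...) {
  m <- x$meta
  cat("Labeled slice dataset:", length(x$images), "images,",
      length(unique(m$subject_id)), "subjects\n")
  sz <- dim(x$images[[1]])
  cat("  image size:", sz[1], "x", sz[2], "\n")
  cat("  stages:", paste(sprintf("%s=%d", levels(m$stage),
                                 tabulate(m$stage, nbins = 3L)),
                         collapse = ", "), "\n")
  if (!is.null(m$split)) {
    cat("  split:", sum(m$split == "train"), "train /",
        sum(m$split == "test"), "test images\n")
  }
  invisible(x)
}

#' Subset a dataset by split assignment
#'
#' @param data an `odss_dataset` with a `split` column.
#' @param split `"train"` or `"test"`.
#' @return an `odss_dataset` restricted to that split.
#' @export
dataset_split <- function(data, split = c("train", "test")) {
  split <- match.arg(split)
  stopifnot(inherits(data, "odss_dataset"))
  if (is.null(data$meta$split)) {
    stop("dataset has no split assignment; call split_by_subject() first",
         call. = FALSE)
  }
  keep <- which(data$meta$split == split)
  odss_dataset(data$images[keep], data$meta[keep, , drop = FALSE])
}

#' Write a dataset to disk as one NIfTI slice per image plus a metadata CSV
#'
#' @param data an `odss_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the metadata table with a `path` column as written.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "odss_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data$meta
  paths <- file.path("images", sprintf("img%04d.nii", seq_along(data$images)))
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  for (i in seq_along(data$images)) {
    write_nifti(data$images[[i]], file.path(dir, paths[i]))
  }
  meta$path <- paths
  meta$severity_s <- if (is.null(meta$severity_s)) NA_real_ else meta$severity_s
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `metadata.csv` and the image files.
#' @return an `odss_dataset`.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv under ", dir, call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  images <- lapply(meta$path, function(p) {
    vol <- load_volume(file.path(dir, p))
    v <- vol$voxels
    if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1L]
    v
  })
  meta$path <- NULL
  odss_dataset(images, meta)
}
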