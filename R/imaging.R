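# Volume ingest: NIfTI loading, mid-coronal slice extraction, intensity
# normalization. Inputs are assumed already preprocessed (skull-stripped,
# template-registered); none of that is done here.

# 1-based plane index of the extracted coronal slice: the printed middle of
# a 137-plane coronal axis. Centralized so it exists in exactly one place.
CORONAL_MIDSLICE <- 69L

#' Load a brain volume (or 2D slice) from a NIfTI-1 file
#'
#' Voxels must be finite; the affine is recorded for provenance only. For a
#' genuinely 3D volume the shape is checked against the expected
#' template-space shape and a mismatch raises a warning, never an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id,stage optional metadata attached to the result.
#' @param expected_shape integer vector the 3D shape is compared against;
#'   default 113 x 137 x 113 (MNI-registered convention).
#' @return an object of class `brain_volume`: fields `voxels`, `subject_id`,
#'   `stage`, `affine`, `path`.
#' @export
load_volume <- function(path, subject_id = NA_character_,
                        stage = NA_character_,
                        expected_shape = c(113L, 137L, 113L)) {
  nii <- read_nifti(path)
  v <- nii$voxels
  n_bad <- sum(!is.finite(v))
  if (n_bad > 0L) {
    stop("volume ", path, " contains ", n_bad, " non-finite voxel(s)",
         call. = FALSE)
  }
  dims <- dim(v)
  if (length(dims) == 3L && dims[3] > 1L && !is.null(expected_shape) &&
      !identical(as.integer(dims), as.integer(expected_shape))) {
    warning("volume shape ", paste(dims, collapse = "x"),
            " differs from expected ",
            paste(expected_shape, collapse = "x"), call. = FALSE)
  }
  structure(list(voxels = v, subject_id = subject_id, stage = stage,
                 affine = nii$affine, path = path),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("Brain volume", paste(dim(x$voxels), collapse = " x "),
      if (!is.na(x$subject_id)) paste0("(subject ", x$subject_id, ")"),
      "\n")
  invisible(x)
}

#' Extract the mid-coronal slice from a 3D volume
#'
#' Returns plane 69 (1-based) along the coronal axis -- the middle plane of
#' a 137-plane axis under the (sagittal, coronal, axial) ordering of
#' MNI-registered volumes. A conformant 113 x 137 x 113 volume yields a
#' 113 x 113 slice.
#'
#' @param volume a `brain_volume` (or bare 3D array).
#' @param coronal_axis which array axis is coronal; default 2.
#' @return the slice as a numeric matrix.
#' @export
extract_coronal_midslice <- function(volume, coronal_axis = 2L) {
  v <- if (inherits(volume, "brain_volume")) volume$voxels else volume
  if (length(dim(v)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(v)), "D", call. = FALSE)
  }
  extent <- dim(v)[coronal_axis]
  if (extent < CORONAL_MIDSLICE) {
    stop("coronal axis has only ", extent, " planes; need at least ",
         CORONAL_MIDSLICE, call. = FALSE)
  }
  idx <- rep(list(quote(expr = )), 3L)
  idx[[coronal_axis]] <- CORONAL_MIDSLICE
  do.call(`[`, c(list(v), idx, list(drop = TRUE)))
}

#' Min-max normalize slice intensities to `[0, 1]`
#'
#' Applied per image (not per dataset) so scanner-scale differences drop
#' out. A constant image maps to all zeros. Idempotent on its own output.
#'
#' @param image numeric matrix with finite entries.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(image) {
  if (!all(is.finite(image))) {
    stop("image contains non-finite pixels", call. = FALSE)
  }
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    return(array(0, dim = dim(image)))
  }
  (image - lo) / (hi - lo)
}
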