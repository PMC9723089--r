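#' CT volume container
#'
#' A minimal container for a scalar 3-D grid in Hounsfield units (HU):
#' a `[rows, cols, slices]` array plus voxel spacing and, for two-level
#' ASPECTS work, the slice level each slice represents.
#'
#' @param data numeric array `[rows, cols, slices]` (a matrix is promoted to
#'   a single-slice volume).
#' @param spacing voxel spacing `(x, y, z)` in mm.
#' @param slice_levels character vector, one of `"ganglionic"` or
#'   `"supraganglionic"` per slice, or `NA` when unknown.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 10), slice_levels = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3)
  if (is.null(slice_levels)) slice_levels <- rep(NA_character_, dim(data)[3])
  stopifnot(length(slice_levels) == dim(data)[3])
  structure(list(data = data, spacing = as.numeric(spacing),
                 slice_levels = slice_levels),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume: %d x %d x %d, spacing (%s) mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

n_slices <- function(vol) dim(vol$data)[3]

#' Extract one slice of a volume as a matrix
#'
#' @param vol a [ct_volume()].
#' @param s slice index.
#' @return numeric matrix.
#' @export
get_slice <- function(vol, s) vol$data[, , s]
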