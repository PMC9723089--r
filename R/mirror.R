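# Mirror assembly: estimate the brain midline, reflect the slice about it,
# and stack (original, mirrored, difference) as the three model input
# channels. The difference channel turns a unilateral hypodensity into a
# signed bilateral signature that is far easier to detect than the raw
# gray-level drop.

#' Estimate the brain midline of a slice
#'
#' Searches reflection axes (angle within +/- 15 degrees of vertical,
#' horizontal offset within +/- 20 px of the image centre) for the one
#' maximizing reflection symmetry of the foreground, scored as the negative
#' mean squared difference between the image and its reflection. The search
#' is coarse-to-fine: a coarse grid on a downsampled image, then two
#' refinement passes at full resolution.
#'
#' @param image numeric matrix (HU); must contain foreground above
#'   `fg_threshold`.
#' @param angle_range,offset_range search half-widths (degrees, pixels).
#' @param fg_threshold HU value separating foreground from air.
#' @return list `(angle, offset)` defining the axis (see
#'   [reflect_image()]).
#' @export
estimate_midline <- function(image, angle_range = 15, offset_range = 20,
                             fg_threshold = -500) {
  if (!any(image > fg_threshold)) stop("empty foreground")
  score <- function(img, angle, offset, bg) {
    ref <- reflect_image(img, list(angle = angle, offset = offset),
                         background = bg)
    -mean((img - ref)^2)
  }
  # coarse pass on a downsampled copy (offsets scale with the image)
  ds <- max(1L, floor(min(dim(image)) / 128))
  small <- if (ds > 1) resize_image(image, ceiling(dim(image) / ds)) else image
  bg <- min(image)
  best <- c(angle = 0, offset = 0)
  best_s <- -Inf
  for (ang in seq(-angle_range, angle_range, by = 3)) {
    for (off in seq(-offset_range, offset_range, by = 2) / ds) {
      s <- score(small, ang, off, bg)
      if (s > best_s) { best_s <- s; best <- c(ang, off * ds) }
    }
  }
  # refinement at full resolution
  for (step in list(c(1, 1), c(0.25, 0.25))) {
    grid_a <- seq(best[1] - 2 * step[1], best[1] + 2 * step[1], by = step[1])
    grid_o <- seq(best[2] - 2 * step[2], best[2] + 2 * step[2], by = step[2])
    best_s <- -Inf
    for (ang in grid_a) {
      for (off in grid_o) {
        s <- score(image, ang, off, bg)
        if (s > best_s) { best_s <- s; best <- c(ang, off) }
      }
    }
  }
  list(angle = unname(best[1]), offset = unname(best[2]))
}

#' Assemble the three-channel mirror input
#'
#' Reflects the slice about the midline axis and subtracts, yielding the
#' channel stack (original, mirrored, difference = original - mirrored).
#' All three channels share the normalization of the input image.
#'
#' @param image numeric matrix (already preprocessed).
#' @param axis midline axis from [estimate_midline()], or `NULL` to assume
#'   the exact image centre (valid for centred phantoms).
#' @param background fill used when reflecting near borders; defaults to
#'   the image minimum.
#' @return object of class `mirror_input`: `original`, `mirrored`,
#'   `difference`, `axis`.
#' @export
make_mirror_input <- function(image, axis = NULL, background = min(image)) {
  if (is.null(axis)) axis <- list(angle = 0, offset = 0)
  mir <- reflect_image(image, axis, background = background)
  structure(list(original = image, mirrored = mir,
                 difference = image - mir, axis = axis),
            class = "mirror_input")
}

# stack a mirror_input into the [h, w, 3] array the network consumes
mirror_array <- function(mi) {
  array(c(mi$original, mi$mirrored, mi$difference),
        c(dim(mi$original), 3))
}
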