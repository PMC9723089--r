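#' 2-D affine transform (rotation, anisotropic scale, translation)
#'
#' Represents the forward map from template coordinates to subject
#' coordinates, `F(p) = R(angle) S (p - c) + c + t`, with `S =
#' diag(sx, sy)` and `c` the rotation centre. Coordinates are 1-based pixel
#' centres `(x = column, y = row)`.
#'
#' @param angle rotation in degrees (counter-clockwise in x-right/y-down
#'   pixel coordinates).
#' @param tx,ty translation in pixels.
#' @param sx,sy scale factors; must be positive.
#' @param center length-2 rotation centre `(x, y)`; typically the image
#'   centre.
#' @return an object of class `affine2d`.
#' @export
affine2d <- function(angle = 0, tx = 0, ty = 0, sx = 1, sy = 1,
                     center = c(0, 0)) {
  stopifnot(sx > 0, sy > 0, length(center) == 2)
  structure(list(angle = angle, tx = tx, ty = ty, sx = sx, sy = sy,
                 center = as.numeric(center)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf(
    "affine2d: angle %.3f deg, t = (%.3f, %.3f) px, scale = (%.4f, %.4f)\n",
    x$angle, x$tx, x$ty, x$sx, x$sy))
  invisible(x)
}

# 2x2 linear part + translation of the forward map, as list(A, t)
affine_forward_matrix <- function(tf) {
  th <- tf$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% diag(c(tf$sx, tf$sy))
  t <- tf$center + c(tf$tx, tf$ty) - A %*% tf$center
  list(A = A, t = as.numeric(t))
}

# pull map (subject coordinate -> template coordinate) of the forward affine
affine_pull_matrix <- function(tf) {
  f <- affine_forward_matrix(tf)
  Ai <- solve(f$A)
  list(A = Ai, t = as.numeric(-Ai %*% f$t))
}

#' Apply an affine transform to a 2-D image
#'
#' Resamples `img` on a grid of size `dim_out` so that
#' `out(q) = img(F^{-1}(q))`: the image content is moved by the forward
#' transform. Out-of-grid samples take `background`.
#'
#' @param img numeric matrix.
#' @param tf an [affine2d()] transform.
#' @param dim_out `c(rows, cols)` of the output; defaults to `dim(img)`.
#' @param interp `"bilinear"` or `"nearest"` (use nearest for label/mask
#'   images so values stay categorical).
#' @param background fill value outside the source grid.
#' @return numeric matrix of size `dim_out`.
#' @export
warp_affine <- function(img, tf, dim_out = dim(img),
                        interp = c("bilinear", "nearest"), background = 0) {
  interp <- match.arg(interp)
  stopifnot(is.matrix(img))
  d <- abs(det(affine_forward_matrix(tf)$A))
  if (d < 1e-6) stop("affine transform is (near) singular")
  p <- affine_pull_matrix(tf)
  affine_sample_cpp(img, as.numeric(p$A), p$t, dim_out[1], dim_out[2],
                    if (interp == "nearest") 1L else 0L, background)
}

# reflection about the line through (cx + offset, cy) with direction
# (sin a, cos a), a in degrees from the vertical; involution, so the pull
# map equals the forward map
reflection_matrix <- function(angle, offset, center) {
  th <- angle * pi / 180
  d <- c(sin(th), cos(th))                   # unit direction of the axis
  P <- c(center[1] + offset, center[2])
  H <- matrix(c(2 * d[1]^2 - 1, 2 * d[1] * d[2],
                2 * d[1] * d[2], 2 * d[2]^2 - 1), 2, 2)
  list(A = H, t = as.numeric(P - H %*% P))
}

#' Reflect an image about a midline axis
#'
#' @param img numeric matrix.
#' @param axis list with `angle` (degrees from vertical) and `offset`
#'   (pixels, signed horizontal shift of the axis from the image centre), as
#'   returned by [estimate_midline()].
#' @param background fill value for samples falling outside the grid.
#' @return reflected image, same size as `img`.
#' @export
reflect_image <- function(img, axis, background = 0) {
  ctr <- (dim(img)[2:1] + 1) / 2              # (x, y) centre
  m <- reflection_matrix(axis$angle, axis$offset, ctr)
  affine_sample_cpp(img, as.numeric(m$A), m$t, nrow(img), ncol(img),
                    0L, background)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param dim_out `c(rows, cols)` of the output grid.
#' @return resized matrix. Pixel centres are mapped proportionally
#'   (half-pixel convention), and edge samples clamp to the border.
#' @export
resize_image <- function(img, dim_out) {
  resize_bilinear_cpp(img, as.integer(dim_out[1]), as.integer(dim_out[2]))
}

#' Nearest-neighbour resize for masks and label images
#'
#' @inheritParams resize_image
#' @return resized matrix whose values are all drawn from `img` (binary
#'   masks stay binary, labels stay labels).
#' @export
resize_nearest <- function(img, dim_out) {
  oh <- as.integer(dim_out[1]); ow <- as.integer(dim_out[2])
  h <- nrow(img); w <- ncol(img)
  A <- diag(c(w / ow, h / oh))
  t <- c(0.5 - 0.5 * w / ow, 0.5 - 0.5 * h / oh)
  out <- affine_sample_cpp(img, as.numeric(A), t, oh, ow, 1L, 0)
  out
}
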