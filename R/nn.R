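# Dual-path segmentation network, written against the package's own
# conv/resize kernels (src/ops.cpp). The global path downsamples to a
# stride-8 grid for coarse lesion localization (ResNeXt-style encoder,
# prediction head on the stage-3 feature map); the local path keeps full
# resolution with a dense skip concatenation (Dense-UNet flavour) for
# boundary detail. Pre-sigmoid scores of both paths are bilinearly resized
# to the target grid, fused by element-wise addition, and squashed, so the
# fused map stays a probability. Width/depth are configurable; the shipped
# "tiny" profile keeps CPU training tractable.

sigmoid <- function(z) 1 / (1 + exp(-z))

conv_layer <- function(inc, outc, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_in <- k * k * inc
  list(W = matrix(rnorm(outc * fan_in, 0, sqrt(2 / fan_in)), outc, fan_in),
       b = numeric(outc),
       inc = inc, outc = outc, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv_fwd <- function(ly, x) {
  d <- dim(x)
  if (d[3] != ly$inc) stop("channel count mismatch: got ", d[3],
                           ", layer expects ", ly$inc)
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3],
                     ly$k, ly$stride, ly$pad)
  oh <- (d[1] + 2L * ly$pad - ly$k) %/% ly$stride + 1L
  ow <- (d[2] + 2L * ly$pad - ly$k) %/% ly$stride + 1L
  out <- ly$W %*% cols + ly$b
  list(out = array(t(out), c(oh, ow, ly$outc)), cols = cols, indim = d)
}

conv_bwd <- function(ly, cache, dout) {
  D <- t(matrix(dout, prod(dim(dout)[1:2]), dim(dout)[3]))
  dW <- D %*% t(cache$cols)
  db <- rowSums(D)
  dx <- col2im_cpp(crossprod(ly$W, D), cache$indim[1], cache$indim[2],
                   cache$indim[3], ly$k, ly$stride, ly$pad)
  list(dW = dW, db = db, dx = dx)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dout) dout * (x > 0)

upsample_fwd <- function(x, oh, ow) {
  c_ <- dim(x)[3]
  out <- array(0, c(oh, ow, c_))
  for (ch in seq_len(c_)) out[, , ch] <- resize_bilinear_cpp(x[, , ch, drop = TRUE], oh, ow)
  out
}

upsample_bwd <- function(dout, ih, iw) {
  c_ <- dim(dout)[3]
  din <- array(0, c(ih, iw, c_))
  for (ch in seq_len(c_)) {
    din[, , ch] <- resize_bilinear_bwd_cpp(dout[, , ch, drop = TRUE], ih, iw)
  }
  din
}

#' Create a dual-path segmentation model
#'
#' @param width base channel width; the shipped profiles are `"tiny"`
#'   (width 8, for CPU-scale experiments and tests) and `"full"` (width
#'   32). Depth is fixed by the architecture: three stride-2 stages on the
#'   global path (stride-8 output) and one down/up stage with a dense skip
#'   on the local path.
#' @param input_size expected square input size (any size divisible by 8
#'   works; 512 matches the full-scale configuration).
#' @param seed RNG seed for weight initialization (He normal).
#' @return object of class `dual_path_model`.
#' @export
dual_path_model <- function(width = 8L, input_size = 64L, seed = 1L) {
  set.seed(seed)
  w <- as.integer(width)
  layers <- list(
    g1 = conv_layer(3L, w, 3L, 2L),        # -> /2
    g2 = conv_layer(w, 2L * w, 3L, 2L),    # -> /4
    g3 = conv_layer(2L * w, 2L * w, 3L, 2L), # -> /8
    gh = conv_layer(2L * w, 1L, 1L, 1L),   # coarse head (stride-8 logits)
    l1 = conv_layer(3L, w, 3L, 1L),
    l2 = conv_layer(w, 2L * w, 3L, 2L),    # -> /2
    l3 = conv_layer(2L * w, 2L * w, 3L, 1L),
    l4 = conv_layer(3L * w, w, 3L, 1L),    # after dense concat [l1 | up(l3)]
    l5 = conv_layer(w, 1L, 1L, 1L)         # full-resolution head
  )
  structure(list(layers = layers, width = w,
                 input_size = as.integer(input_size), trained = FALSE),
            class = "dual_path_model")
}

#' @export
print.dual_path_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("dual_path_model: width %d, input %d, %d parameters, %s\n",
              x$width, x$input_size, np,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Global-path forward pass (coarse stride-8 probabilities)
#'
#' @param model a [dual_path_model()].
#' @param x input array `[h, w, 3]` (original, mirrored, difference).
#' @return probability matrix on the `h/8` x `w/8` grid.
#' @export
global_path_forward <- function(model, x) {
  f <- forward_global(model$layers, x)
  sigmoid(f$logits[, , 1])
}

#' Local-path forward pass (full-resolution probabilities)
#'
#' @inheritParams global_path_forward
#' @return probability matrix on the input grid.
#' @export
local_path_forward <- function(model, x) {
  f <- forward_local(model$layers, x)
  sigmoid(f$logits[, , 1])
}

forward_global <- function(L, x) {
  a1 <- conv_fwd(L$g1, x);  r1 <- relu_fwd(a1$out)
  a2 <- conv_fwd(L$g2, r1); r2 <- relu_fwd(a2$out)
  a3 <- conv_fwd(L$g3, r2); r3 <- relu_fwd(a3$out)
  ah <- conv_fwd(L$gh, r3)
  list(logits = ah$out,
       cache = list(a1 = a1, a2 = a2, a3 = a3, ah = ah,
                    r1 = r1, r2 = r2, r3 = r3))
}

forward_local <- function(L, x) {
  b1 <- conv_fwd(L$l1, x);  s1 <- relu_fwd(b1$out)
  b2 <- conv_fwd(L$l2, s1); s2 <- relu_fwd(b2$out)
  b3 <- conv_fwd(L$l3, s2); s3 <- relu_fwd(b3$out)
  h <- dim(s1)[1]; w <- dim(s1)[2]
  up <- upsample_fwd(s3, h, w)
  cc <- array(c(s1, up), c(h, w, dim(s1)[3] + dim(up)[3]))
  b4 <- conv_fwd(L$l4, cc); s4 <- relu_fwd(b4$out)
  bh <- conv_fwd(L$l5, s4)
  list(logits = bh$out,
       cache = list(b1 = b1, b2 = b2, b3 = b3, b4 = b4, bh = bh,
                    s1 = s1, s2 = s2, s3 = s3, s4 = s4, up = up, cc = cc))
}

# full forward pass; target_dim defaults to the input grid
model_forward <- function(model, x, target_dim = dim(x)[1:2]) {
  L <- model$layers
  g <- forward_global(L, x)
  l <- forward_local(L, x)
  gup <- resize_bilinear_cpp(g$logits[, , 1], target_dim[1], target_dim[2])
  lup <- if (all(dim(l$logits)[1:2] == target_dim)) l$logits[, , 1]
         else resize_bilinear_cpp(l$logits[, , 1], target_dim[1], target_dim[2])
  z <- gup + lup
  list(prob = sigmoid(z), logits = z, global = g, local = l,
       target_dim = target_dim)
}

# backward pass from d(loss)/d(fused logits); returns gradients keyed like
# model$layers
model_backward <- function(model, fw, dz) {
  L <- model$layers
  G <- list()
  # global branch: fused grad -> coarse grid -> head -> encoder
  gdim <- dim(fw$global$logits)
  dg <- array(resize_bilinear_bwd_cpp(dz, gdim[1], gdim[2]), gdim)
  cg <- fw$global$cache
  bh <- conv_bwd(L$gh, cg$ah, dg);            G$gh <- bh
  d3 <- relu_bwd(cg$a3$out, bh$dx)
  b3 <- conv_bwd(L$g3, cg$a3, d3);            G$g3 <- b3
  d2 <- relu_bwd(cg$a2$out, b3$dx)
  b2 <- conv_bwd(L$g2, cg$a2, d2);            G$g2 <- b2
  d1 <- relu_bwd(cg$a1$out, b2$dx)
  G$g1 <- conv_bwd(L$g1, cg$a1, d1)
  # local branch
  cl <- fw$local$cache
  ldim <- dim(cl$bh$out)
  dl <- if (all(ldim[1:2] == dim(dz))) array(dz, ldim)
        else array(resize_bilinear_bwd_cpp(dz, ldim[1], ldim[2]), ldim)
  lh <- conv_bwd(L$l5, cl$bh, dl);            G$l5 <- lh
  d4 <- relu_bwd(cl$b4$out, lh$dx)
  l4 <- conv_bwd(L$l4, cl$b4, d4);            G$l4 <- l4
  wch <- dim(cl$s1)[3]
  dcc <- l4$dx
  ds1_cat <- dcc[, , seq_len(wch), drop = FALSE]
  dup <- dcc[, , -seq_len(wch), drop = FALSE]
  ds3 <- upsample_bwd(dup, dim(cl$s3)[1], dim(cl$s3)[2])
  d3l <- relu_bwd(cl$b3$out, ds3)
  l3 <- conv_bwd(L$l3, cl$b3, d3l);           G$l3 <- l3
  d2l <- relu_bwd(cl$b2$out, l3$dx)
  l2 <- conv_bwd(L$l2, cl$b2, d2l);           G$l2 <- l2
  ds1 <- ds1_cat + l2$dx
  d1l <- relu_bwd(cl$b1$out, ds1)
  G$l1 <- conv_bwd(L$l1, cl$b1, d1l)
  G
}

#' Fused forward pass on one prepared input
#'
#' Runs both pathways on a single three-channel input array and returns
#' the fused probability map on the input grid.
#'
#' @param model a [dual_path_model()].
#' @param x input array `[h, w, 3]` (see [make_training_set()]).
#' @return probability matrix in `[0, 1]`.
#' @export
predict_slice_prob <- function(model, x) {
  model_forward(model, x)$prob
}

#' Fuse the two pathway outputs
#'
#' Both pathways' pre-sigmoid scores are bilinearly resized to the target
#' grid, added element-wise, and squashed with the logistic function, so
#' identical logits `l` from both paths yield `sigmoid(2 l)` and the result
#' always stays in `[0, 1]`.
#'
#' @param global_logits coarse-path logit matrix.
#' @param local_logits local-path logit matrix.
#' @param target_dim `c(rows, cols)` of the fused output grid.
#' @return probability matrix in `[0, 1]`.
#' @export
fuse <- function(global_logits, local_logits, target_dim) {
  g <- resize_bilinear_cpp(global_logits, target_dim[1], target_dim[2])
  l <- resize_bilinear_cpp(local_logits, target_dim[1], target_dim[2])
  sigmoid(g + l)
}

#' Combined cross-entropy + Dice loss
#'
#' `total = ce_term + dice_term` with unit weights: `ce_term` is the mean
#' binary cross-entropy and `dice_term = 1 - (2 sum(p t) + eps) /
#' (sum(p) + sum(t) + eps)` with smoothing `eps = 1`, so an empty truth
#' matched by an empty prediction scores a Dice term of 0.
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param truth binary matrix of the same size.
#' @param eps Dice smoothing constant.
#' @param ce_weight,dice_weight term weights (default 1:1).
#' @return object of class `loss_value`: `total`, `ce_term`, `dice_term`.
#' @export
combined_loss <- function(pred, truth, eps = 1, ce_weight = 1,
                          dice_weight = 1) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (!all(truth %in% c(0, 1))) stop("truth mask must be binary")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  ce <- -mean(truth * log(p) + (1 - truth) * log(1 - p))
  inter <- sum(pred * truth)
  dice <- 1 - (2 * inter + eps) / (sum(pred) + sum(truth) + eps)
  structure(list(total = ce_weight * ce + dice_weight * dice,
                 ce_term = ce, dice_term = dice),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("loss: total %.4f (ce %.4f + dice %.4f)\n",
              x$total, x$ce_term, x$dice_term))
  invisible(x)
}

# gradient of the combined loss w.r.t. the fused logits
loss_grad_logits <- function(prob, truth, eps = 1, ce_weight = 1,
                             dice_weight = 1) {
  n <- length(prob)
  dce <- (prob - truth) / n
  S <- sum(prob) + sum(truth) + eps
  I2 <- 2 * sum(prob * truth) + eps
  ddice_dp <- -(2 * truth * S - I2) / S^2
  ddice <- ddice_dp * prob * (1 - prob)
  ce_weight * dce + dice_weight * ddice
}
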