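# Training loop (SGD + stepped learning-rate decay, early stopping on the
# validation loss) and volume-level prediction.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: SGD from `lr0 = 0.002` with a
#' stepped decay (factor 0.1 every 30 epochs), up to 100 epochs on
#' 512 x 512 inputs, stopping early once the validation loss starts to
#' increase (patience 5 epochs). CPU-scale experiments override `epochs`,
#' `input_size` and `lr0` via the `tiny` profile of [train_config_tiny()].
#'
#' @param lr0 initial learning rate (> 0).
#' @param lr_factor,lr_step stepped decay: `lr(e) = lr0 * lr_factor^floor(e
#'   / lr_step)` for 0-based epoch `e`.
#' @param epochs maximum epochs (>= 1).
#' @param batch_size slices per SGD update (gradients averaged).
#' @param momentum SGD momentum.
#' @param input_size square model input size.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping.
#' @param ce_weight,dice_weight loss term weights (default 1:1).
#' @param seed RNG seed for shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr0 = 0.002, lr_factor = 0.1, lr_step = 30L,
                         epochs = 100L, batch_size = 8L, momentum = 0.9,
                         input_size = 512L,
                         patience = 5L, ce_weight = 1, dice_weight = 1,
                         seed = 1L) {
  stopifnot(lr0 > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr0 = lr0, lr_factor = lr_factor,
                 lr_step = as.integer(lr_step),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 input_size = as.integer(input_size),
                 patience = as.integer(patience),
                 ce_weight = ce_weight, dice_weight = dice_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' CPU-scale ("tiny") training profile
#'
#' Small inputs, higher learning rate and few epochs: enough for the
#' phantom cohorts this package trains on, and fast enough for desk-scale
#' runs. The architecture is unchanged; only capacity and schedule shrink.
#'
#' @param epochs maximum epochs.
#' @param input_size square input size (divisible by 8).
#' @param seed RNG seed.
#' @param ... further overrides passed to [train_config()].
#' @export
train_config_tiny <- function(epochs = 45L, input_size = 64L, seed = 1L, ...) {
  train_config(lr0 = 0.05, lr_factor = 0.5, lr_step = 15L, epochs = epochs,
               batch_size = 8L, input_size = input_size, patience = 10L,
               seed = seed, ...)
}

#' Learning rate at a given epoch
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return `lr0 * lr_factor^floor(epoch / lr_step)`.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr0 * cfg$lr_factor^(epoch %/% cfg$lr_step)
}

# prepare one slice into the 3-channel model input
prepare_slice_input <- function(slice, input_size, midline = c("center", "estimate"),
                                median_kernel = 3L, gamma = 0.6,
                                window = c(0, 80)) {
  midline <- match.arg(midline)
  enh <- preprocess_slice(slice, median_kernel, gamma, window)
  enh <- resize_image(enh, c(input_size, input_size))
  axis <- if (midline == "estimate") {
    # estimate on the HU slice (foreground detection needs HU), then reuse:
    # offsets scale with the resize factor
    ax <- estimate_midline(slice)
    ax$offset <- ax$offset * input_size / ncol(slice)
    ax
  } else NULL
  x <- mirror_array(make_mirror_input(enh, axis, background = 0))
  # centre the image channels about the mid-window intensity so all three
  # channels are near zero-mean (the difference channel already is)
  x[, , 1] <- x[, , 1] - 0.5
  x[, , 2] <- x[, , 2] - 0.5
  x
}

# cohort -> per-slice training examples (x: [n,n,3], y: [n,n] binary)
#' Build per-slice training examples from a phantom cohort
#'
#' @param cohort result of [generate_cohort()].
#' @param input_size model input size.
#' @param midline `"center"` (phantoms are centred) or `"estimate"`.
#' @return list of examples, each `list(x, y, case_id, slice)`.
#' @export
make_training_set <- function(cohort, input_size = 64L,
                              midline = "center") {
  out <- list()
  for (cs in cohort$cases) {
    for (s in seq_len(n_slices(cs$volume))) {
      x <- prepare_slice_input(get_slice(cs$volume, s), input_size, midline)
      y <- resize_nearest(cs$lesion_mask[, , s], c(input_size, input_size))
      out[[length(out) + 1L]] <- list(x = x, y = y, case_id = cs$case_id,
                                      slice = s)
    }
  }
  out
}

sgd_step <- function(model, vel, grads, lr, momentum) {
  for (nm in names(grads)) {
    vel[[nm]]$W <- momentum * vel[[nm]]$W + grads[[nm]]$dW
    vel[[nm]]$b <- momentum * vel[[nm]]$b + grads[[nm]]$db
    model$layers[[nm]]$W <- model$layers[[nm]]$W - lr * vel[[nm]]$W
    model$layers[[nm]]$b <- model$layers[[nm]]$b - lr * vel[[nm]]$b
  }
  list(model = model, vel = vel)
}

eval_split <- function(model, split, cfg) {
  ce <- 0; dice <- 0
  for (ex in split) {
    fw <- model_forward(model, ex$x)
    l <- combined_loss(fw$prob, ex$y, ce_weight = cfg$ce_weight,
                       dice_weight = cfg$dice_weight)
    ce <- ce + l$ce_term; dice <- dice + l$dice_term
  }
  c(ce = ce / length(split), dice = dice / length(split))
}

#' Train the dual-path model
#'
#' Plain SGD with momentum over single-slice steps, the stepped
#' learning-rate decay of `cfg`, and early stopping once the validation
#' loss has not improved for `cfg$patience` consecutive epochs. The
#' best-validation parameters are returned.
#'
#' @param model a [dual_path_model()].
#' @param train_set,val_set example lists from [make_training_set()]; both
#'   must be nonempty.
#' @param cfg a [train_config()].
#' @param max_steps optional hard cap on total SGD steps (used by the
#'   overfit wiring check).
#' @return list `model` (best checkpoint, `trained = TRUE`) and `trace`
#'   (data.frame epoch, lr, train_ce, train_dice, val_ce, val_dice).
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        max_steps = Inf) {
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("empty train or validation split")
  }
  set.seed(cfg$seed)
  vel <- lapply(model$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  best <- list(loss = Inf, model = model)
  bad <- 0L; steps <- 0L
  rows <- list()
  for (e in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, e - 1L)
    ord <- sample(length(train_set))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tr_ce <- 0; tr_dice <- 0
    for (bi in batches) {
      acc <- NULL
      for (i in bi) {
        ex <- train_set[[i]]
        fw <- model_forward(model, ex$x)
        l <- combined_loss(fw$prob, ex$y, ce_weight = cfg$ce_weight,
                           dice_weight = cfg$dice_weight)
        tr_ce <- tr_ce + l$ce_term; tr_dice <- tr_dice + l$dice_term
        dz <- loss_grad_logits(fw$prob, ex$y, ce_weight = cfg$ce_weight,
                               dice_weight = cfg$dice_weight)
        g <- model_backward(model, fw, dz)
        if (is.null(acc)) acc <- g
        else for (nm in names(acc)) {
          acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
          acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$dW <- acc[[nm]]$dW / length(bi)
        acc[[nm]]$db <- acc[[nm]]$db / length(bi)
      }
      st <- sgd_step(model, vel, acc, lr, cfg$momentum)
      model <- st$model; vel <- st$vel
      steps <- steps + 1L
      if (steps >= max_steps) break
    }
    val <- eval_split(model, val_set, cfg)
    vloss <- sum(val)
    rows[[e]] <- data.frame(epoch = e, lr = lr,
                            train_ce = tr_ce / length(train_set),
                            train_dice = tr_dice / length(train_set),
                            val_ce = val["ce"], val_dice = val["dice"])
    if (vloss < best$loss) {
      best <- list(loss = vloss, model = model)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
    if (steps >= max_steps) break
  }
  out <- best$model
  out$trained <- TRUE
  out$config <- cfg
  list(model = out, trace = do.call(rbind, rows))
}

#' Segment a volume and map probabilities back to the source grid
#'
#' Runs the full per-slice pipeline (median filter, dark-detail
#' enhancement, resample to the model input, mirror assembly, dual-path
#' forward pass, fusion) and resizes the fused probability map back to the
#' original slice grid. Thresholding, when requested, happens after the
#' map returns to the source grid.
#'
#' @param model a trained [dual_path_model()].
#' @param volume a [ct_volume()].
#' @param threshold optional probability cut `t*` producing a binary mask
#'   (see [calibrate_threshold()]).
#' @param midline `"center"` or `"estimate"`.
#' @return list `prob` (`[H, W, S]` array in `[0, 1]`) and, when
#'   `threshold` is given, `mask` (same grid, 0/1).
#' @export
predict_volume <- function(model, volume, threshold = NULL,
                           midline = "center") {
  if (!isTRUE(model$trained)) stop("model is untrained")
  d <- dim(volume$data)
  prob <- array(0, d)
  for (s in seq_len(d[3])) {
    x <- prepare_slice_input(get_slice(volume, s), model$input_size, midline)
    fw <- model_forward(model, x)
    prob[, , s] <- resize_image(fw$prob, d[1:2])
  }
  prob <- pmin(pmax(prob, 0), 1)
  out <- list(prob = prob)
  if (!is.null(threshold)) out$mask <- array((prob > threshold) * 1L, d)
  out
}

#' Save / load a model checkpoint
#'
#' Self-describing checkpoint: configuration, width, input size and all
#' layer weights.
#'
#' @param model a [dual_path_model()].
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(class = "dual_path_model", width = model$width,
               input_size = model$input_size, trained = model$trained,
               config = model$config, layers = model$layers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(layers = ck$layers, width = ck$width,
                 input_size = ck$input_size, trained = ck$trained,
                 config = ck$config),
            class = "dual_path_model")
}
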