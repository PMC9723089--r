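# Dual-path network: shapes, fusion, loss identities, gradients, training
# loop mechanics.

test_that("pathway outputs have the contracted grids and ranges", {
  m <- dual_path_model(width = 4, input_size = 32, seed = 2)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  g <- global_path_forward(m, x)
  expect_equal(dim(g), c(4, 4))              # stride-8 grid
  expect_true(all(g >= 0 & g <= 1))
  l <- local_path_forward(m, x)
  expect_equal(dim(l), c(32, 32))            # full resolution
  expect_true(all(l >= 0 & l <= 1))
  # wrong channel count is rejected
  expect_error(global_path_forward(m, array(0, c(32, 32, 2))), "channel")
})

test_that("fusion adds pre-sigmoid scores and saturates safely", {
  l <- matrix(rnorm(64), 8, 8)
  fused <- fuse(l, l, c(8, 8))
  expect_equal(fused, 1 / (1 + exp(-2 * l)))
  # one silent pathway: fused is the sigmoid of the other's resized logits
  z <- matrix(rnorm(16), 4, 4)
  f2 <- fuse(matrix(0, 4, 4), z, c(8, 8))
  expect_equal(f2, 1 / (1 + exp(-resize_image(z, c(8, 8)))))
  # adversarially large logits stay inside [0, 1]
  f3 <- fuse(matrix(1e6, 4, 4), matrix(-1e6, 8, 8), c(8, 8))
  expect_true(all(f3 >= 0 & f3 <= 1))
})

test_that("combined loss decomposes exactly and matches closed forms", {
  # perfect hard prediction
  t1 <- matrix(c(1, 0, 0, 1), 2, 2)
  l1 <- combined_loss(t1, t1)
  expect_equal(l1$dice_term, 0)
  expect_lt(l1$ce_term, 1e-5)
  expect_equal(l1$total, l1$ce_term + l1$dice_term)

  # empty truth, empty prediction: smoothing gives a zero Dice term
  z <- matrix(0, 4, 4)
  expect_equal(combined_loss(z, z)$dice_term, 0)

  # half-positive truth against a uniform 0.5 prediction, N = 64
  N <- 64
  tr <- matrix(rep(c(0, 1), each = N / 2), 8, 8)
  pr <- matrix(0.5, 8, 8)
  l <- combined_loss(pr, tr)
  expect_equal(l$ce_term, log(2))
  expect_equal(l$dice_term,
               1 - (2 * 0.5 * N / 2 + 1) / (0.5 * N + N / 2 + 1))

  expect_error(combined_loss(pr, tr * 0.5), "binary")
  expect_error(combined_loss(pr, matrix(0, 4, 4)), "shape")
})

test_that("backpropagation matches numeric gradients", {
  set.seed(3)
  m <- dual_path_model(width = 2, input_size = 16, seed = 3)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fw <- aspectsct:::model_forward(m, x)
  dz <- aspectsct:::loss_grad_logits(fw$prob, y)
  gr <- aspectsct:::model_backward(m, fw, dz)
  eps <- 1e-5
  for (nm in names(m$layers)) {
    W <- m$layers[[nm]]$W
    for (i in sample(length(W), min(3, length(W)))) {
      mp <- m; mp$layers[[nm]]$W[i] <- W[i] + eps
      mm <- m; mm$layers[[nm]]$W[i] <- W[i] - eps
      lp <- combined_loss(aspectsct:::model_forward(mp, x)$prob, y)$total
      lm <- combined_loss(aspectsct:::model_forward(mm, x)$prob, y)$total
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - gr[[nm]]$dW[i]) / max(1e-6, abs(num)), 1e-3)
    }
  }
})

test_that("the learning-rate schedule is the stepped decay of the config", {
  cfg <- train_config(lr0 = 0.002, lr_factor = 0.1, lr_step = 30)
  for (e in c(0, 1, 29, 30, 59, 60, 99)) {
    expect_equal(lr_at_epoch(cfg, e), 0.002 * 0.1^(e %/% 30))
  }
  expect_error(train_config(lr0 = 0), "lr0")
})

test_that("training is deterministic and early stopping guards the best model", {
  spec <- small_spec(64)
  co <- generate_cohort(3, prevalence = 0.3, spec = spec, seed = 5,
                        random_affine = FALSE, atlas = small_atlas(64))
  ex <- make_training_set(co, input_size = 32)
  m <- dual_path_model(width = 2, input_size = 32, seed = 1)
  cfg <- train_config_tiny(epochs = 3, input_size = 32, seed = 1)
  f1 <- train_model(m, ex, ex, cfg)
  f2 <- train_model(m, ex, ex, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$layers, f2$model$layers)
  expect_true(f1$model$trained)
  expect_error(train_model(m, list(), ex, cfg), "empty")
  # untrained model refuses to predict
  expect_error(predict_volume(m, co$cases[[1]]$volume), "untrained")
})

test_that("checkpoints round-trip through disk", {
  m <- dual_path_model(width = 2, input_size = 32, seed = 4)
  m$trained <- TRUE
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$layers, m$layers)
  expect_equal(m2$width, m$width)
  unlink(p)
})
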