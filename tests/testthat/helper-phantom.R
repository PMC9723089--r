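# Shared fixtures: everything is generated in code at test time. The
# small atlas/spec pair is cached per test run since several files use it.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(size = 128) phantom_spec(image_size = size)

small_atlas <- function(size = 128) {
  key <- paste0("atlas_", size)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_template_atlas(small_spec(size))
  }
  .fixtures[[key]]
}

# toy ROC cases built from explicit per-region probability plateaus: each
# region's pixels all carry probability p_k, so its calling score is p_k;
# regions beyond the requested outcomes get truth NA (excluded)
toy_roc_cases <- function(scores, truths) {
  at <- small_atlas(64)
  stopifnot(length(scores) == length(truths))
  cases <- list()
  i <- 1L
  while (i <= length(scores)) {
    take <- seq(i, min(i + 19, length(scores)))
    prob <- array(0, dim(at$labels))
    truth <- rep(NA_integer_, 20)
    for (j in seq_along(take)) {
      prob[at$labels == j] <- scores[take[j]]
      truth[j] <- truths[take[j]]
    }
    cases[[length(cases) + 1L]] <-
      list(prob = prob, labels = at$labels, truth = truth)
    i <- i + 20L
  }
  cases
}
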