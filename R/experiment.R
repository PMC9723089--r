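# Self-contained phantom learning experiment: generate cohorts, train the
# tiny dual-path model, calibrate the thresholds on a validation split,
# then score held-out subjects through atlas registration. This is the
# package's reference end-to-end run at desk scale.

#' Run the phantom learning experiment end to end
#'
#' Generates a training cohort and an independent held-out cohort of
#' two-level brain phantoms, trains the dual-path segmentation model,
#' calibrates the probability/overlap thresholds by region-level Youden
#' index on the validation split, and evaluates held-out region calls with
#' atlas registration in the loop (atlas to subject, labels by nearest
#' neighbour).
#'
#' @param n_train training-cohort cases (two slices each).
#' @param n_test held-out cases.
#' @param seed master seed for cohorts, initialization and shuffling.
#' @param image_size phantom grid size in pixels.
#' @param input_size model input size.
#' @param width model channel width.
#' @param epochs training epochs (tiny schedule).
#' @param prevalence per-region lesion rate.
#' @param n_val validation slices held out of the training cohort.
#' @return list: `accuracy` (held-out region-call accuracy), `auc` (pooled
#'   region ROC AUC), `calibration` (`t_star`, `tau_star`, ...), `model`,
#'   `trace`, `roc`, `confusion` (held-out TP/FP/TN/FN).
#' @export
run_learning_experiment <- function(n_train = 100, n_test = 30, seed = 1L,
                                    image_size = 128L, input_size = 64L,
                                    width = 8L, epochs = 45L,
                                    prevalence = 0.1, n_val = 40L) {
  spec <- phantom_spec(image_size = image_size)
  atlas <- build_template_atlas(spec)
  co_tr <- generate_cohort(n_train, prevalence = prevalence, spec = spec,
                           seed = seed + 100L, atlas = atlas)
  co_te <- generate_cohort(n_test, prevalence = prevalence, spec = spec,
                           seed = seed + 200L, atlas = atlas)

  ex <- make_training_set(co_tr, input_size = input_size)
  set.seed(seed)
  ord <- sample(length(ex))
  val <- ex[ord[seq_len(n_val)]]
  tr <- ex[ord[-seq_len(n_val)]]

  model <- dual_path_model(width = width, input_size = input_size,
                           seed = seed)
  cfg <- train_config_tiny(epochs = epochs, input_size = input_size,
                           seed = seed)
  fit <- train_model(model, tr, val, cfg)

  # calibrate on the cases contributing validation slices
  val_ids <- unique(vapply(val, function(e) e$case_id, ""))
  val_cases <- Filter(function(cs) cs$case_id %in% val_ids, co_tr$cases)
  probs <- lapply(val_cases, function(cs) {
    predict_volume(fit$model, cs$volume)$prob
  })
  cal <- calibrate_threshold(probs,
                             lapply(val_cases, `[[`, "labels"),
                             do.call(rbind, lapply(val_cases, `[[`,
                                                   "true_scores")))

  # held-out evaluation with registration in the loop
  conf <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  roc_cases <- list()
  for (cs in co_te$cases) {
    pred <- predict_volume(fit$model, cs$volume)
    reg <- register_atlas(atlas, cs$volume)
    sc <- score_case(pred$prob, reg$labels, cal$t_star, cal$tau_star)
    conf["tp"] <- conf["tp"] + sum(sc$calls == 1 & cs$true_scores == 1)
    conf["fp"] <- conf["fp"] + sum(sc$calls == 1 & cs$true_scores == 0)
    conf["tn"] <- conf["tn"] + sum(sc$calls == 0 & cs$true_scores == 0)
    conf["fn"] <- conf["fn"] + sum(sc$calls == 0 & cs$true_scores == 1)
    roc_cases[[length(roc_cases) + 1L]] <-
      list(prob = pred$prob, labels = reg$labels, truth = cs$true_scores)
  }
  roc <- region_roc(roc_cases, tau = cal$tau_star)
  list(accuracy = (conf[["tp"]] + conf[["tn"]]) / sum(conf),
       auc = roc$auc, calibration = cal, model = fit$model,
       trace = fit$trace, roc = roc, confusion = conf)
}
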