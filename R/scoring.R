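# ASPECTS scoring: lesion/territory overlap proportions, binary region
# calls, per-hemisphere totals, and joint calibration of the probability
# and overlap thresholds on a validation cohort.

#' Lesion overlap proportion per ASPECTS region
#'
#' `rho_k = |lesion n region_k| / |region_k|`: the fraction of each
#' territory involved by the lesion. Regions absent from the scanned
#' levels get `rho = 0` and are flagged.
#'
#' @param lesion binary array (or matrix) on the subject grid.
#' @param labels integer label array on the same grid.
#' @return list `rho` (20 proportions), `region_px` (territory sizes),
#'   `flagged` (logical, territory empty on this grid).
#' @export
overlap_proportions <- function(lesion, labels) {
  if (!all(dim(lesion) == dim(labels))) stop("grids disagree")
  lab <- as.integer(labels)
  region_px <- tabulate(lab, nbins = 20)
  hit <- tabulate(lab[lesion > 0], nbins = 20)
  rho <- ifelse(region_px > 0, hit / region_px, 0)
  flagged <- region_px == 0
  if (any(flagged)) {
    warning("coverage: ", sum(flagged),
            " region(s) absent from the scanned levels; their scores are flagged")
  }
  list(rho = rho, region_px = region_px, flagged = flagged)
}

#' Convert overlap proportions into region calls and ASPECTS
#'
#' A region is called positive when its overlap proportion exceeds `tau`;
#' each hemisphere's ASPECTS is 10 minus its positive-region count.
#'
#' @param rho 20 overlap proportions (or the list from
#'   [overlap_proportions()]).
#' @param tau region-positivity threshold in `[0, 1)`; default 0.05
#'   (any clear involvement deducts the point) until calibration overrides
#'   it.
#' @return object of class `region_score_vector`: `rho`, `calls`, `tau`,
#'   `aspects_left`, `aspects_right`.
#' @export
score_regions <- function(rho, tau = 0.05) {
  if (is.list(rho)) rho <- rho$rho
  stopifnot(length(rho) == 20, tau >= 0, tau < 1)
  calls <- as.integer(rho > tau)
  structure(list(rho = rho, calls = calls, tau = tau,
                 aspects_left = 10L - sum(calls[1:10]),
                 aspects_right = 10L - sum(calls[11:20])),
            class = "region_score_vector")
}

#' @export
print.region_score_vector <- function(x, ...) {
  cat(sprintf("ASPECTS left %d / right %d (tau = %g, %d region(s) called)\n",
              x$aspects_left, x$aspects_right, x$tau, sum(x$calls)))
  invisible(x)
}

#' Region score table for a scored case
#'
#' @param scores a `region_score_vector`.
#' @param case_id case identifier.
#' @return data.frame `case_id`, `region_label`, `region_name`, `side`,
#'   `rho`, `call`, `tau`.
#' @export
region_score_table <- function(scores, case_id = "case") {
  tab <- aspects_label_table()
  data.frame(case_id = case_id, region_label = tab$label,
             region_name = tab$name, side = tab$side,
             rho = scores$rho, call = scores$calls, tau = scores$tau,
             stringsAsFactors = FALSE)
}

# rho_k as a function of the probability threshold grid:
# rho_k(t) = fraction of region-k pixels with prob > t -> [20 x length(t)]
region_rho_curve <- function(prob, labels, t_grid) {
  lab <- as.integer(labels)
  region_px <- tabulate(lab, nbins = 20)
  out <- matrix(0, 20, length(t_grid))
  p <- as.numeric(prob)
  for (k in which(region_px > 0)) {
    pk <- p[lab == k]
    out[k, ] <- vapply(t_grid, function(t) mean(pk > t), 0)
  }
  out
}

#' Calibrate the probability and overlap thresholds
#'
#' Joint grid search over the segmentation probability cut `t` and the
#' region-positivity cut `tau`, maximizing the region-level Youden index
#' (TPR - FPR) pooled over all case-region outcomes of a validation
#' cohort. The segmentation threshold is thus chosen for region-level
#' ASPECTS accuracy, not for voxel-level Dice. Ties break toward higher
#' specificity, then lower `t`.
#'
#' @param probs list of probability arrays, one per case.
#' @param labels_list list of matching subject-space label arrays.
#' @param truth matrix `[n_cases, 20]` of true region scores (0/1).
#' @param t_grid probability thresholds to scan.
#' @param tau_grid overlap thresholds to scan.
#' @return list `t_star`, `tau_star`, `youden`, `tpr`, `fpr`, and the full
#'   `grid` data.frame.
#' @export
calibrate_threshold <- function(probs, labels_list, truth,
                                t_grid = seq(0.05, 0.95, by = 0.05),
                                tau_grid = c(0.01, 0.025, 0.05, 0.1, 0.15,
                                             0.2, 0.3, 0.4, 0.5)) {
  stopifnot(length(probs) == length(labels_list),
            nrow(truth) == length(probs))
  if (length(unique(as.integer(truth))) < 2) {
    stop("calibration error: single-class region truth")
  }
  n <- length(probs)
  rho <- array(0, c(n, 20, length(t_grid)))
  for (i in seq_len(n)) {
    rho[i, , ] <- region_rho_curve(probs[[i]], labels_list[[i]], t_grid)
  }
  tv <- as.integer(truth)
  rows <- list()
  best <- NULL
  for (ti in seq_along(t_grid)) {
    for (tau in tau_grid) {
      calls <- as.integer(rho[, , ti] > tau)
      tp <- sum(calls == 1 & tv == 1); fn <- sum(calls == 0 & tv == 1)
      fp <- sum(calls == 1 & tv == 0); tn <- sum(calls == 0 & tv == 0)
      tpr <- tp / (tp + fn); fpr <- fp / (fp + tn)
      cand <- list(t_star = t_grid[ti], tau_star = tau,
                   youden = tpr - fpr, tpr = tpr, fpr = fpr)
      rows[[length(rows) + 1L]] <- as.data.frame(cand)
      if (is.null(best) ||
          cand$youden > best$youden + 1e-12 ||
          (abs(cand$youden - best$youden) <= 1e-12 &&
           (cand$fpr < best$fpr - 1e-12 ||
            (abs(cand$fpr - best$fpr) <= 1e-12 &&
             cand$t_star < best$t_star)))) {
        best <- cand
      }
    }
  }
  c(best, list(grid = do.call(rbind, rows)))
}

#' Score a predicted segmentation against a registered atlas
#'
#' Pipeline convenience: threshold the probability map at `t`, compute
#' overlap proportions against the subject-space labels, and call regions
#' at `tau`.
#'
#' @param prob probability array on the subject grid.
#' @param labels subject-space label array.
#' @param t probability threshold.
#' @param tau overlap threshold.
#' @return a `region_score_vector`.
#' @export
score_case <- function(prob, labels, t, tau = 0.05) {
  mask <- (prob > t) * 1L
  score_regions(overlap_proportions(mask, labels), tau)
}
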