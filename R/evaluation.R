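# Region-based ROC/AUC, segmentation metrics, and the multi-reader
# statistics battery: ICC (two-way, single rater, absolute agreement),
# McNemar, paired t, and jackknife confidence intervals.

#' Region-based ROC curve
#'
#' Enumerates probability thresholds on a fixed grid; at each threshold
#' every case-region outcome is called positive when its lesion overlap
#' proportion exceeds `tau`, and TPR/FPR are pooled over all outcomes
#' (20 per case). AUC is the trapezoid over the swept (FPR, TPR) path,
#' which on any finite instance equals the Mann-Whitney
#' probability-of-correct-ranking of the per-region calling scores.
#'
#' @param cases list of cases, each `list(prob, labels, truth)` with a
#'   probability array, matching label array, and 20 true region scores
#'   (`NA` marks a region absent from the scanned levels; such outcomes
#'   are excluded from pooling).
#' @param tau overlap threshold for region positivity.
#' @param thresholds probability grid (default 101 points on `[0, 1]`).
#' @return object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
region_roc <- function(cases, tau = 0.05,
                       thresholds = seq(0, 1, length.out = 101)) {
  rho_list <- lapply(cases, function(cs) {
    region_rho_curve(cs$prob, cs$labels, thresholds)
  })
  truth_list <- lapply(cases, `[[`, "truth")
  pooled_roc(rho_list, truth_list, tau, thresholds)
}

# pool precomputed per-case rho-vs-threshold matrices into one ROC
pooled_roc <- function(rho_list, truth_list, tau, thresholds) {
  truth <- unlist(truth_list)
  keep <- !is.na(truth)
  truth <- truth[keep]
  if (length(unique(truth)) < 2) stop("single-class region truth")
  rho <- do.call(rbind, rho_list)[keep, , drop = FALSE]
  pos <- truth == 1
  tpr <- colMeans(rho[pos, , drop = FALSE] > tau)
  fpr <- colMeans(rho[!pos, , drop = FALSE] > tau)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = trapezoid_auc(fpr, tpr)),
            class = "roc_curve")
}

# trapezoid over the ROC path, endpoints (0,0) and (1,1) included
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Bootstrap confidence interval for the region-based AUC
#'
#' Case-level nonparametric bootstrap (resampling whole cases preserves
#' the within-case correlation of the 20 region outcomes), percentile
#' interval. Replicates whose resample is single-class are redrawn.
#'
#' @param cases as in [region_roc()].
#' @param tau overlap threshold.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list `auc`, `low`, `high`, `n_boot`, `widened` (TRUE when fewer
#'   than 10 cases were available).
#' @export
auc_ci <- function(cases, tau = 0.05, n_boot = 2000, seed = 1L,
                   conf = 0.95) {
  set.seed(seed)
  thresholds <- seq(0, 1, length.out = 101)
  rho_list <- lapply(cases, function(cs) {
    region_rho_curve(cs$prob, cs$labels, thresholds)
  })
  truth_list <- lapply(cases, `[[`, "truth")
  point <- pooled_roc(rho_list, truth_list, tau, thresholds)$auc
  n <- length(cases)
  widened <- n < 10
  if (widened) warning("fewer than 10 cases: bootstrap CI is unstable")
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample(n, replace = TRUE)
      truth <- unlist(truth_list[idx])
      if (length(unique(truth[!is.na(truth)])) >= 2) break
    }
    reps[b] <- pooled_roc(rho_list[idx], truth_list[idx], tau,
                          thresholds)$auc
  }
  a <- (1 - conf) / 2
  ci <- quantile(reps, c(a, 1 - a), names = FALSE)
  list(auc = point, low = min(ci[1], point), high = max(ci[2], point),
       n_boot = n_boot, widened = widened)
}

#' Segmentation metrics: Dice, precision, recall
#'
#' `dsc = 2TP / (2TP + FP + FN)`, `precision = TP / (TP + FP)`, `recall =
#' TP / (TP + FN)`. Conventions for empty denominators: if both masks are
#' empty all three metrics are 1 (perfect agreement on absence); an empty
#' denominator with disagreement elsewhere yields 0.
#'
#' @param pred,truth binary arrays on the same grid.
#' @return object of class `seg_metrics`: `dsc`, `precision`, `recall`,
#'   plus the `tp`, `fp`, `fn` tallies.
#' @export
seg_metrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  p <- pred > 0; t <- truth > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    m <- list(dsc = 1, precision = 1, recall = 1)
  } else {
    m <- list(dsc = 2 * tp / (2 * tp + fp + fn),
              precision = if (tp + fp > 0) tp / (tp + fp) else 0,
              recall = if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  structure(c(m, list(tp = tp, fp = fp, fn = fn)), class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("DSC %.3f, precision %.3f, recall %.3f\n",
              x$dsc, x$precision, x$recall))
  invisible(x)
}

#' Intraclass correlation, two-way, single rater, absolute agreement
#'
#' ICC(A,1): `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the
#' two-way (cases x raters) mean squares, including systematic rater
#' offsets in the disagreement.
#'
#' @param table numeric matrix or data.frame, rows = cases (or case-region
#'   outcomes), columns = raters; `n >= 2` rows and `k >= 2` columns.
#' @return list `icc`, `msr`, `msc`, `mse`, `n`, `k`.
#' @export
icc_agreement <- function(table) {
  y <- as.matrix(table)
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("need at least 2 cases and 2 raters")
  if (var(as.numeric(y)) == 0) {
    stop("degenerate input: zero variance across all ratings")
  }
  g <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((y - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' McNemar test from discordant counts
#'
#' For `b + c >= 25` uses the chi-squared approximation `(b - c)^2 /
#' (b + c)` on 1 df (no continuity correction); otherwise the exact
#' two-sided binomial(b + c, 1/2) test. `b + c = 0` returns p = 1 with a
#' degenerate flag.
#'
#' @param b,c discordant pair counts.
#' @return list `statistic` (chi-squared, or NA for the exact branch),
#'   `p_value`, `method`, `degenerate`.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  nd <- b + c
  if (nd == 0) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (nd >= 25) {
    stat <- (b - c)^2 / nd
    list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
         method = "chi-squared", degenerate = FALSE)
  } else {
    p <- min(1, 2 * pbinom(min(b, c), nd, 0.5))
    list(statistic = NA_real_, p_value = p, method = "exact binomial",
         degenerate = FALSE)
  }
}

#' Paired t test on per-case values
#'
#' @param x,y numeric vectors of equal length >= 2 (e.g. per-session
#'   reading times).
#' @return list `t`, `p_value`, `mean_diff`, `degenerate` (TRUE when the
#'   differences have zero variance, in which case t = 0 and p = 1).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    return(list(t = 0, p_value = 1, mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Jackknife confidence interval for an aggregate statistic
#'
#' Leave-one-out pseudovalues `n * stat(all) - (n-1) * stat(minus i)`;
#' the SE is the SD of the pseudovalues over `sqrt(n)` and the CI the
#' normal approximation. For the mean the jackknife SE equals `s / sqrt(n)`
#' exactly.
#'
#' @param values per-case statistic contributions.
#' @param stat aggregator function (default `mean`).
#' @param conf confidence level.
#' @return list `estimate`, `se`, `low`, `high`.
#' @export
jackknife_ci <- function(values, stat = mean, conf = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  full <- stat(values)
  ps <- vapply(seq_len(n),
               function(i) n * full - (n - 1) * stat(values[-i]), 0)
  est <- mean(ps)
  se <- sd(ps) / sqrt(n)
  z <- qnorm(1 - (1 - conf) / 2)
  list(estimate = est, se = se, low = est - z * se, high = est + z * se)
}

#' Simulate reader rating tables for a cohort
#'
#' Emulates region-level binary calls by raters with given sensitivity and
#' specificity, plus per-case reading times — the synthetic stand-in for a
#' multi-reader session used to exercise the statistics battery.
#'
#' @param manifest cohort manifest (`case_id`, `region_label`,
#'   `true_score`).
#' @param n_raters number of raters.
#' @param sens,spec per-rater sensitivity/specificity (recycled).
#' @param time_mean,time_sd per-case reading time distribution (seconds).
#' @param session session label attached to the table.
#' @param seed RNG seed.
#' @return list `ratings` (data.frame `case_id`, `region_label`, `truth`,
#'   `session`, `rater_1..k`) and `times` (data.frame `case_id`, `rater`,
#'   `session`, `seconds`).
#' @export
simulate_ratings <- function(manifest, n_raters = 4, sens = 0.3,
                             spec = 0.9, time_mean = 219, time_sd = 40,
                             session = "baseline", seed = 1L) {
  set.seed(seed)
  sens <- rep(sens, length.out = n_raters)
  spec <- rep(spec, length.out = n_raters)
  truth <- manifest$true_score
  ratings <- data.frame(case_id = manifest$case_id,
                        region_label = manifest$region_label,
                        truth = truth, session = session,
                        stringsAsFactors = FALSE)
  for (r in seq_len(n_raters)) {
    pr <- ifelse(truth == 1, sens[r], 1 - spec[r])
    ratings[[paste0("rater_", r)]] <- rbinom(length(truth), 1, pr)
  }
  ids <- unique(manifest$case_id)
  times <- expand.grid(case_id = ids, rater = seq_len(n_raters),
                       stringsAsFactors = FALSE)
  times$session <- session
  times$seconds <- pmax(30, rnorm(nrow(times), time_mean, time_sd))
  list(ratings = ratings, times = times)
}

#' Per-rater and average reader performance
#'
#' Region-based sensitivity and specificity per rater, averages with
#' jackknife CIs over cases, and (when two sessions are present) McNemar
#' comparisons of each rater's calls between sessions. Rows with missing
#' entries are excluded and counted.
#'
#' @param ratings rating table as produced by [simulate_ratings()] (long
#'   format with `truth`, `session`, `rater_*` columns).
#' @return list `per_rater` (data.frame), `average` (sens/spec with CIs
#'   per session), `mcnemar` (between-session comparisons, if applicable),
#'   `n_excluded`.
#' @export
reader_metrics <- function(ratings) {
  rater_cols <- grep("^rater_", names(ratings), value = TRUE)
  if (length(rater_cols) == 0) stop("no rater_* columns")
  keep <- stats::complete.cases(ratings[c("truth", rater_cols)])
  n_excluded <- sum(!keep)
  ratings <- ratings[keep, ]
  sessions <- unique(ratings$session)
  per <- list(); avg <- list()
  for (ss in sessions) {
    tab <- ratings[ratings$session == ss, ]
    for (rc in rater_cols) {
      pos <- tab$truth == 1
      sens <- mean(tab[[rc]][pos] == 1)
      spec <- mean(tab[[rc]][!pos] == 0)
      per[[length(per) + 1L]] <- data.frame(session = ss, rater = rc,
                                            sensitivity = sens,
                                            specificity = spec)
    }
    # per-case contributions to the average reader sensitivity/specificity
    ids <- unique(tab$case_id)
    case_stat <- function(id, truth_val, correct_val) {
      sub <- tab[tab$case_id == id & tab$truth == truth_val, ]
      if (nrow(sub) == 0) return(NA_real_)
      mean(unlist(sub[rater_cols]) == correct_val)
    }
    sens_c <- vapply(ids, case_stat, 0, truth_val = 1, correct_val = 1)
    spec_c <- vapply(ids, case_stat, 0, truth_val = 0, correct_val = 0)
    sens_ci <- jackknife_ci(sens_c[!is.na(sens_c)])
    spec_ci <- jackknife_ci(spec_c[!is.na(spec_c)])
    avg[[length(avg) + 1L]] <- data.frame(
      session = ss,
      sensitivity = sens_ci$estimate, sens_low = sens_ci$low,
      sens_high = sens_ci$high,
      specificity = spec_ci$estimate, spec_low = spec_ci$low,
      spec_high = spec_ci$high)
  }
  out <- list(per_rater = do.call(rbind, per),
              average = do.call(rbind, avg),
              n_excluded = n_excluded)
  if (length(sessions) == 2) {
    mc <- list()
    key <- c("case_id", "region_label")
    s1 <- ratings[ratings$session == sessions[1], ]
    s2 <- ratings[ratings$session == sessions[2], ]
    m <- merge(s1, s2, by = key, suffixes = c("_1", "_2"))
    for (rc in rater_cols) {
      for (tv in c(1, 0)) {
        sub <- m[m$truth_1 == tv, ]
        ok1 <- sub[[paste0(rc, "_1")]] == tv
        ok2 <- sub[[paste0(rc, "_2")]] == tv
        b <- sum(ok1 & !ok2); cc <- sum(!ok1 & ok2)
        t <- mcnemar_test(b, cc)
        mc[[length(mc) + 1L]] <- data.frame(
          rater = rc, metric = if (tv == 1) "sensitivity" else "specificity",
          b = b, c = cc, p_value = t$p_value, method = t$method)
      }
    }
    out$mcnemar <- do.call(rbind, mc)
  }
  out
}
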