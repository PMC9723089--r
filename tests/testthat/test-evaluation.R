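# Region-based ROC, segmentation metrics, and the reader-study statistics
# battery, each checked against an independent oracle where one exists.

test_that("perfectly informative probability maps give AUC 1", {
  cs <- toy_roc_cases(scores = c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15),
                      truths = c(1, 1, 1, 0, 0, 0))
  roc <- region_roc(cs, tau = 0.05)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$tpr) <= 0))       # monotone along the sweep
  expect_true(all(diff(roc$fpr) <= 0))
})

test_that("AUC equals the Mann-Whitney oracle on small instances", {
  # scores on grid points so the enumerated sweep resolves every value
  set.seed(31)
  for (rep in 1:5) {
    sc <- sample(seq(0.1, 0.9, by = 0.1), 8, replace = TRUE)
    tr <- c(1, 1, 1, 0, 0, 0, 1, 0)
    cs <- toy_roc_cases(sc, tr)
    roc <- region_roc(cs, tau = 0.05)
    pos <- sc[tr == 1]; neg <- sc[tr == 0]
    mw <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_lt(abs(roc$auc - mw), 1e-12)
  }
})

test_that("uninformative scores give AUC near one half at n = 2000", {
  set.seed(32)
  n <- 2000
  sc <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)
  tr <- rbinom(n, 1, 0.3)
  cs <- toy_roc_cases(sc, tr)
  roc <- region_roc(cs, tau = 0.05)
  expect_lt(abs(roc$auc - 0.5), 0.03)
  expect_error(region_roc(toy_roc_cases(c(0.2, 0.4), c(1, 1))),
               "single-class")
})

test_that("bootstrap AUC interval behaves and shrinks with n", {
  mk <- function(n, seed) {
    set.seed(seed)
    sc <- pmin(pmax(rnorm(n, 0.4 + 0.25 * rbinom(n, 1, 0.5), 0.15), 0), 1)
    tr <- as.integer(sc > 0.5)
    tr[sample(n, n %/% 5)] <- 1 - tr[sample(n, n %/% 5)]  # add noise
    toy_roc_cases(sc, tr)
  }
  widths <- vapply(c(60, 240, 960), function(n) {
    ci <- suppressWarnings(auc_ci(mk(n, n), n_boot = 200, seed = 1))
    expect_true(ci$low <= ci$auc && ci$auc <= ci$high)
    expect_true(ci$low >= 0 && ci$high <= 1)
    ci$high - ci$low
  }, 0)
  expect_true(all(diff(widths) < 0))        # roughly 1/sqrt(n) shrinkage
  # degenerate separable data: the upper bound reaches 1
  sep <- toy_roc_cases(c(0.9, 0.9, 0.1, 0.1, 0.9, 0.1),
                       c(1, 1, 0, 0, 1, 0))
  ci1 <- suppressWarnings(auc_ci(sep, n_boot = 50, seed = 2))
  expect_equal(ci1$high, 1)
  expect_true(ci1$widened)
})

test_that("segmentation metrics reproduce the printed identities", {
  # subset-mask construction: truth 1000 px, prediction a 616-px subset
  truth <- array(0L, c(50, 40))
  truth[seq_len(1000)] <- 1L
  pred <- array(0L, c(50, 40))
  pred[seq_len(616)] <- 1L
  m <- seg_metrics(pred, truth)
  expect_equal(m$precision, 1.000)
  expect_equal(m$recall, 0.616)
  expect_equal(round(m$dsc, 3), 0.762)

  pred2 <- array(0L, c(50, 40))
  pred2[seq_len(690)] <- 1L
  m2 <- seg_metrics(pred2, truth)
  expect_equal(round(m2$dsc, 3), 0.817)
  expect_equal(m2$recall, 0.690)

  # identical nonempty masks
  mm <- seg_metrics(truth, truth)
  expect_equal(c(mm$dsc, mm$precision, mm$recall), c(1, 1, 1))
  # both empty: all 1 by convention
  e <- seg_metrics(truth * 0L, truth * 0L)
  expect_equal(c(e$dsc, e$precision, e$recall), c(1, 1, 1))
  expect_error(seg_metrics(pred[1:10, ], truth), "shape")
})

test_that("Dice is the harmonic mean of precision and recall when defined", {
  set.seed(33)
  for (i in 1:10) {
    a <- array(rbinom(400, 1, 0.3), c(20, 20))
    b <- array(rbinom(400, 1, 0.3), c(20, 20))
    m <- seg_metrics(a, b)
    if (m$precision + m$recall > 0) {
      expect_equal(m$dsc,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("ICC(A,1) matches a from-scratch two-way ANOVA decomposition", {
  # perfect agreement
  y <- matrix(rep(1:6, 4), 6, 4)
  expect_equal(icc_agreement(y)$icc, 1)

  # oracle: mean squares from stats::aov on the long layout
  set.seed(34)
  for (n in c(6, 20, 50)) {
    y <- matrix(rnorm(n * 4), n, 4) + rnorm(n)          # case effects
    y <- sweep(y, 2, c(0, 0.3, -0.2, 0.1), "+")          # rater offsets
    long <- data.frame(y = as.numeric(y),
                       case = factor(rep(seq_len(n), 4)),
                       rater = factor(rep(1:4, each = n)))
    ms <- summary(stats::aov(y ~ case + rater, data = long))[[1]]
    msr <- ms["case", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
    mse <- ms["Residuals", "Mean Sq"]
    k <- 4
    oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    expect_lt(abs(icc_agreement(y)$icc - oracle), 1e-10)
  }

  # independent ratings: ICC near zero
  set.seed(35)
  y0 <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(icc_agreement(y0)$icc), 0.05)

  expect_error(icc_agreement(matrix(1, 5, 3)), "degenerate")
  expect_error(icc_agreement(matrix(rnorm(3), 3, 1)), "at least 2")
})

test_that("McNemar handles exact, asymptotic and degenerate branches", {
  m0 <- mcnemar_test(5, 5)
  expect_equal(m0$p_value, 1)
  expect_true(m0$method == "exact binomial")

  m1 <- mcnemar_test(30, 10)
  expect_equal(m1$statistic, 10)
  expect_equal(m1$p_value, pchisq(10, 1, lower.tail = FALSE))

  # exact two-sided binomial: b = 8, c = 1
  m2 <- mcnemar_test(8, 1)
  expect_equal(m2$p_value, 2 * sum(choose(9, 0:1)) / 2^9)
  expect_equal(round(m2$p_value, 4), 0.0391)

  md <- mcnemar_test(0, 0)
  expect_true(md$degenerate)
  expect_equal(md$p_value, 1)

  # chi-squared and exact p agree near the branch point
  for (bc in list(c(17, 8), c(15, 10), c(13, 12))) {
    exact <- mcnemar_test(bc[1], bc[2])$p_value
    stat <- (bc[1] - bc[2])^2 / sum(bc)
    approx <- pchisq(stat, 1, lower.tail = FALSE)
    expect_lt(abs(exact - approx), 0.1)
  }
})

test_that("paired t matches the closed form and flags degeneracy", {
  # differences (1, 2, 3, 4): t = mean / (sd / sqrt(n)) = 3.873
  x <- c(11, 22, 33, 44); y <- x - (1:4)
  r <- paired_t(x, y)
  d <- 1:4
  expect_equal(r$t, mean(d) / (sd(d) / 2))
  expect_equal(round(r$t, 3), 3.873)

  r2 <- paired_t(y, x)
  expect_equal(r2$t, -r$t)                   # antisymmetry

  r0 <- paired_t(x, x)
  expect_true(r0$degenerate)
  expect_equal(r0$t, 0)
})

test_that("jackknife CI reduces to s/sqrt(n) for the mean", {
  set.seed(36)
  v <- rnorm(40, 10, 3)
  ci <- jackknife_ci(v)
  expect_equal(ci$estimate, mean(v))
  expect_equal(ci$se, sd(v) / sqrt(40))
  expect_true(ci$low <= ci$estimate && ci$estimate <= ci$high)
  # identical contributions: zero-width interval
  c0 <- jackknife_ci(rep(2, 10))
  expect_equal(c0$low, c0$high)
  expect_error(jackknife_ci(1), "at least 2")
})

test_that("reader metrics recover per-rater and average performance", {
  spec <- small_spec(64)
  co <- generate_cohort(30, prevalence = 0.25, spec = spec, seed = 41,
                        random_affine = FALSE, atlas = small_atlas(64))
  rt <- simulate_ratings(co$manifest, n_raters = 2, sens = 1, spec = 1,
                         seed = 1)$ratings
  # a perfect rater: sensitivity = specificity = 1
  rm <- reader_metrics(rt)
  expect_true(all(rm$per_rater$sensitivity == 1))
  expect_true(all(rm$per_rater$specificity == 1))

  # an inverted rater: both zero
  rt2 <- rt
  rt2$rater_1 <- 1 - rt2$truth
  rt2$rater_2 <- 1 - rt2$truth
  rm2 <- reader_metrics(rt2)
  expect_true(all(rm2$per_rater$sensitivity == 0))
  expect_true(all(rm2$per_rater$specificity == 0))

  # printed 2x2 tally arithmetic: TP 30 / FN 70, TN 180 / FP 20
  tally <- data.frame(
    case_id = rep(sprintf("c%02d", 1:30), length.out = 300),
    region_label = rep(1:10, 30),
    truth = rep(c(1, 0), c(100, 200)),
    session = "baseline",
    rater_1 = c(rep(c(1, 0), c(30, 70)), rep(c(0, 1), c(180, 20))))
  rm3 <- reader_metrics(tally)
  expect_equal(rm3$per_rater$sensitivity, 0.30)
  expect_equal(rm3$per_rater$specificity, 0.90)

  # two sessions produce McNemar comparisons
  two <- rbind(rt, within(rt, session <- "aided"))
  rm4 <- reader_metrics(two)
  expect_true(!is.null(rm4$mcnemar))
  expect_true(all(rm4$mcnemar$p_value == 1))  # identical sessions
})
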