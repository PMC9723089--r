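# ASPECTS scoring: overlap proportions, region calls, threshold
# calibration.

test_that("overlap proportions count pixels correctly", {
  at <- small_atlas(128)
  lab <- at$labels
  # lesion covering all of left L
  les <- array(0L, dim(lab))
  les[lab == region_label("L", "left")] <- 1L
  ov <- overlap_proportions(les, lab)
  expect_equal(ov$rho[region_label("L", "left")], 1)
  expect_equal(sum(ov$rho), 1)
  # empty intersection
  ov0 <- overlap_proportions(array(0L, dim(lab)), lab)
  expect_true(all(ov0$rho == 0))
  expect_error(overlap_proportions(les[1:10, 1:10, 1, drop = FALSE], lab),
               "disagree")
  # single-slice grid: the other level's regions are flagged
  expect_warning(
    ovf <- overlap_proportions(les[, , 1], lab[, , 1]),
    "flagged")
  expect_true(all(ovf$flagged[aspects_label_table()$level ==
                                "supraganglionic"]))
})

test_that("region calls and ASPECTS follow the threshold logic", {
  rho <- numeric(20)
  s0 <- score_regions(rho, tau = 0.1)
  expect_equal(s0$aspects_left, 10L)
  expect_equal(s0$aspects_right, 10L)

  rho[region_label("L", "left")] <- 1
  s1 <- score_regions(rho, tau = 0.1)
  expect_equal(s1$aspects_left, 9L)
  expect_equal(s1$aspects_right, 10L)

  rho2 <- numeric(20)
  rho2[region_label("M5", "left")] <- 0.30
  rho2[region_label("IC", "left")] <- 0.15
  s2 <- score_regions(rho2, tau = 0.2)
  expect_equal(sum(s2$calls), 1L)
  expect_equal(s2$calls[region_label("M5", "left")], 1L)
  expect_equal(s2$aspects_left, 9L)
})

test_that("raising tau never adds calls and never lowers ASPECTS", {
  set.seed(21)
  rho <- runif(20, 0, 0.6)
  taus <- seq(0, 0.9, by = 0.05)
  prev <- score_regions(rho, 0)
  for (tau in taus[-1]) {
    cur <- score_regions(rho, tau)
    expect_true(all(cur$calls <= prev$calls))
    expect_gte(cur$aspects_left, prev$aspects_left)
    expect_gte(cur$aspects_right, prev$aspects_right)
    prev <- cur
  }
})

test_that("calls and ASPECTS conserve the 20 regions", {
  set.seed(22)
  for (i in 1:20) {
    s <- score_regions(runif(20), tau = runif(1, 0, 0.9))
    expect_equal(sum(s$calls) + s$aspects_left + s$aspects_right, 20)
  }
})

test_that("threshold calibration is exact on separable synthetic scores", {
  at <- small_atlas(64)
  # two cases: positives carry probability 0.9 in their regions,
  # negatives 0.1 -> perfectly separable at t in (0.1, 0.9)
  mkcase <- function(pos) {
    prob <- array(0, dim(at$labels))
    for (k in 1:20) prob[at$labels == k] <- if (k %in% pos) 0.9 else 0.1
    truth <- integer(20); truth[pos] <- 1L
    list(prob = prob, truth = truth)
  }
  cs <- lapply(list(c(1, 5), c(12, 18, 3)), mkcase)
  cal <- calibrate_threshold(lapply(cs, `[[`, "prob"),
                             list(at$labels, at$labels),
                             do.call(rbind, lapply(cs, `[[`, "truth")))
  expect_equal(cal$tpr, 1)
  expect_equal(cal$fpr, 0)
  expect_equal(cal$youden, 1)

  # deterministic, and identical to brute force over the same grid
  cal2 <- calibrate_threshold(lapply(cs, `[[`, "prob"),
                              list(at$labels, at$labels),
                              do.call(rbind, lapply(cs, `[[`, "truth")))
  expect_identical(cal[c("t_star", "tau_star")],
                   cal2[c("t_star", "tau_star")])
  best_row <- cal$grid[order(-cal$grid$youden, cal$grid$fpr,
                             cal$grid$t_star), ][1, ]
  expect_equal(best_row$youden, cal$youden)

  # single-class truth is rejected
  expect_error(
    calibrate_threshold(lapply(cs, `[[`, "prob"),
                        list(at$labels, at$labels),
                        matrix(0L, 2, 20)),
    "calibration error")
})
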