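# Synthetic phantom: atlas geometry, subject simulation, lesion insertion,
# cohort generation.

test_that("atlas partitions the brain interior with mirror-symmetric labels", {
  at <- small_atlas(128)
  for (s in 1:2) {
    lab <- at$labels[, , s]
    tmpl <- get_slice(at$template, s)
    # every in-brain pixel (tissue intensity, not skull/air) is labelled
    brain <- tmpl < 500 & tmpl > -500
    expect_true(all(lab[brain] >= 1 & lab[brain] <= 20))
    expect_true(all(lab[!brain] == 0))
    # flipping about the midline maps each label to its contralateral twin
    flipped <- lab[, ncol(lab):1]
    partner <- ifelse(flipped == 0L, 0L,
                      ifelse(flipped > 10L, flipped - 10L, flipped + 10L))
    expect_identical(partner, lab)
  }
  # expected level composition: C/I/IC/L/M1-M3 ganglionic, M4-M6 supra
  tab <- aspects_label_table()
  gang <- sort(unique(as.integer(at$labels[, , 1])))
  expect_setequal(setdiff(gang, 0L),
                  tab$label[tab$level == "ganglionic"])
  supra <- sort(unique(as.integer(at$labels[, , 2])))
  expect_setequal(setdiff(supra, 0L),
                  tab$label[tab$level == "supraganglionic"])
})

test_that("region areas match the analytic sector/annulus areas within 2%", {
  spec <- small_spec(512)
  at <- build_template_atlas(spec)
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  r <- c(0.18, 0.28, 0.38, 0.48)          # C | IC | L | I breakpoints
  # closed-form pixel areas per hemisphere (half of each full figure)
  ann <- function(r0, r1) pi * a * b * (r1^2 - r0^2) / 2
  expected <- c(C = ann(0, r[1]), IC = ann(r[1], r[2]), L = ann(r[2], r[3]),
                I = ann(r[3], r[4]),
                M = a * b * (pi / 6) * (1 - r[4]^2),   # each of M1..M3
                Msup = a * b * pi / 6)                 # each of M4..M6
  counts <- tabulate(at$labels, 20)
  tol <- 0.02
  for (nm in c("C", "I", "IC", "L")) {
    for (side in c("left", "right")) {
      k <- region_label(nm, side)
      expect_lt(abs(counts[k] - expected[[nm]]) / expected[[nm]], tol)
    }
  }
  for (nm in c("M1", "M2", "M3")) {
    for (side in c("left", "right")) {
      k <- region_label(nm, side)
      expect_lt(abs(counts[k] - expected[["M"]]) / expected[["M"]], tol)
    }
  }
  for (nm in c("M4", "M5", "M6")) {
    for (side in c("left", "right")) {
      k <- region_label(nm, side)
      expect_lt(abs(counts[k] - expected[["Msup"]]) / expected[["Msup"]], tol)
    }
  }
})

test_that("atlas rejects grids too small to host the regions", {
  expect_error(build_template_atlas(phantom_spec(image_size = 32)),
               "too small")
})

test_that("subject simulation is seeded and its transform is recoverable", {
  at <- small_atlas(128)
  spec <- small_spec(128)
  s1 <- simulate_subject(at, spec, seed = 5)
  s2 <- simulate_subject(at, spec, seed = 5)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$transform, s2$transform)
  # identity transform: subject = template + noise only
  s0 <- simulate_subject(at, spec, seed = 1,
                         transform = affine2d(center = at$center))
  resid <- s0$volume$data - at$template$data
  expect_lt(max(abs(resid)), 6 * spec$tissue_noise_sd)
  # re-applying the returned transform to the template reproduces the
  # noiseless subject within interpolation error
  s3 <- simulate_subject(at, spec, seed = 9, noise = FALSE)
  rewarp <- warp_affine(get_slice(at$template, 1), s3$transform,
                        background = spec$air_hu)
  expect_lt(mean(abs(rewarp - get_slice(s3$volume, 1))), 1)
})

test_that("lesion insertion hits the requested fill and stores the truth", {
  at <- small_atlas(128)
  spec <- small_spec(128)
  vol <- ct_volume(at$template$data, slice_levels = at$slice_levels)

  # zero-depth lesion leaves everything untouched
  spec0 <- spec; spec0$lesion_regions <- region_label("L", "left")
  spec0$lesion_delta <- 0
  cs0 <- insert_lesion(vol, at$labels, spec0, seed = 1)
  expect_identical(cs0$volume$data, vol$data)
  expect_equal(sum(cs0$lesion_mask), 0)
  expect_equal(cs0$true_aspects_left, 10L)
  expect_equal(cs0$true_aspects_right, 10L)

  # full coverage of one region scores exactly that region
  spec1 <- spec; spec1$lesion_regions <- region_label("L", "left")
  spec1$lesion_fill <- 1
  cs1 <- insert_lesion(vol, at$labels, spec1, seed = 1)
  ov <- overlap_proportions(cs1$lesion_mask, at$labels)
  expect_equal(ov$rho[region_label("L", "left")], 1)
  expect_equal(sum(ov$rho[-region_label("L", "left")]), 0)
  expect_equal(cs1$true_aspects_left, 9L)
  expect_equal(cs1$true_aspects_right, 10L)

  # half fill on M5 measured by pixel counting
  spec2 <- spec; spec2$lesion_regions <- region_label("M5", "right")
  spec2$lesion_fill <- 0.5
  cs2 <- insert_lesion(vol, at$labels, spec2, seed = 3)
  k <- region_label("M5", "right")
  frac <- sum(cs2$lesion_mask[at$labels == k]) / sum(at$labels == k)
  expect_lt(abs(frac - 0.5), 0.02)
  # the hypodensity is applied inside the mask
  delta <- cs2$volume$data - vol$data
  expect_true(all(delta[cs2$lesion_mask == 1] == spec2$lesion_delta))
  expect_true(all(delta[cs2$lesion_mask == 0] == 0))
})

test_that("lesion preconditions are enforced", {
  at <- small_atlas(128)
  spec <- small_spec(128)
  spec$lesion_regions <- region_label("C", "left")
  spec$lesion_fill <- 0
  vol <- ct_volume(at$template$data)
  expect_error(insert_lesion(vol, at$labels, spec), "lesion_fill")
  expect_error(phantom_spec(lesion_delta = 5), "hypodense")
})

test_that("cohorts are reproducible and match the requested prevalence", {
  spec <- small_spec(64)
  at <- small_atlas(64)
  co1 <- generate_cohort(6, prevalence = 0.2, spec = spec, seed = 11,
                         random_affine = FALSE, atlas = at)
  co2 <- generate_cohort(6, prevalence = 0.2, spec = spec, seed = 11,
                         random_affine = FALSE, atlas = at)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$cases[[3]]$volume$data, co2$cases[[3]]$volume$data)

  # prevalence 0: every case scores 10/10
  co0 <- generate_cohort(5, prevalence = 0, spec = spec, seed = 2,
                         random_affine = FALSE, atlas = at)
  expect_true(all(vapply(co0$cases, `[[`, 0L, "true_aspects_left") == 10L))
  expect_true(all(vapply(co0$cases, `[[`, 0L, "true_aspects_right") == 10L))

  # binomial bound on the positive-region count at n = 500
  co <- generate_cohort(500, prevalence = 0.1, spec = spec, seed = 7,
                        random_affine = FALSE, atlas = at)
  npos <- sum(co$manifest$true_score)
  mu <- 0.1 * 500 * 20
  sd3 <- 3 * sqrt(500 * 20 * 0.1 * 0.9)
  expect_lt(abs(npos - mu), sd3)

  # stored ASPECTS is consistent with the stored region truth
  for (cs in co1$cases) {
    expect_equal(cs$true_aspects_left, 10L - sum(cs$true_scores[1:10]))
    expect_equal(cs$true_aspects_right, 10L - sum(cs$true_scores[11:20]))
  }
})
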