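# Synthetic brain phantoms: a programmatic two-level ASPECTS territory
# atlas, subject volumes under known affines, fuzzy hypodense lesions, and
# reproducible cohorts with ground-truth masks and region scores.

#' ASPECTS region label table
#'
#' Labels 1-10 are the left-hemisphere regions C (caudate), I (insula),
#' IC (internal capsule), L (lentiform) and M1-M6 (frontal operculum,
#' anterior/posterior temporal lobe, anterior/lateral/posterior MCA
#' cortex); labels 11-20 are the right counterparts in the same order.
#' C, I, IC, L and M1-M3 live on the ganglionic slice level, M4-M6 on the
#' supraganglionic level.
#'
#' @return data.frame with columns `label`, `name`, `side`, `level`.
#' @export
aspects_label_table <- function() {
  nm <- c("C", "I", "IC", "L", "M1", "M2", "M3", "M4", "M5", "M6")
  lv <- c(rep("ganglionic", 7), rep("supraganglionic", 3))
  data.frame(label = 1:20,
             name = rep(nm, 2),
             side = rep(c("left", "right"), each = 10),
             level = rep(lv, 2),
             stringsAsFactors = FALSE)
}

#' Look up an ASPECTS region label by name and side
#'
#' @param name region name, e.g. `"M5"` or `"IC"`.
#' @param side `"left"` or `"right"`.
#' @return integer label in 1-20.
#' @export
region_label <- function(name, side = c("left", "right")) {
  side <- match.arg(side)
  tab <- aspects_label_table()
  hit <- tab$label[tab$name == name & tab$side == side]
  if (length(hit) != 1) stop("unknown ASPECTS region: ", name)
  hit
}

#' Phantom generation parameters
#'
#' Defines the geometry and intensity statistics of the synthetic brain
#' phantom: a skull ellipse enclosing near-symmetric "tissue" at
#' `tissue_mean` HU with Gaussian noise, imaged at the two ASPECTS slice
#' levels. Lesions are unilateral hypodense blobs (`lesion_delta` < 0 HU)
#' with fuzzy, noise-grown boundaries, emulating the subtle early ischemic
#' change that motivates mirror-difference inputs.
#'
#' @param image_size pixels per axis (square slices); at least 64.
#' @param brain_axes ellipse semi-axes `(a_x, a_y)` in pixels; default
#'   scales with `image_size`.
#' @param tissue_mean mean brain tissue attenuation in HU.
#' @param tissue_noise_sd per-pixel Gaussian noise SD in HU.
#' @param skull_hu attenuation of the skull ring in HU.
#' @param air_hu background attenuation in HU.
#' @param lesion_regions integer vector of target region labels (1-20); see
#'   [aspects_label_table()].
#' @param lesion_delta HU offset added inside the lesion; must be <= 0
#'   (hypodense) for ischemia emulation.
#' @param lesion_fill fraction of each target region covered by the lesion,
#'   in `[0, 1]`.
#' @param seed integer RNG seed used by generators that take no explicit
#'   seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512,
                         brain_axes = NULL,
                         tissue_mean = 35,
                         tissue_noise_sd = 2,
                         skull_hu = 700,
                         air_hu = -1000,
                         lesion_regions = integer(0),
                         lesion_delta = -8,
                         lesion_fill = 0.8,
                         seed = 1L) {
  if (image_size <= 0) stop("image_size must be positive")
  if (is.null(brain_axes)) brain_axes <- image_size * c(0.38, 0.46)
  if (lesion_fill < 0 || lesion_fill > 1) stop("lesion_fill must be in [0, 1]")
  if (lesion_delta > 0) {
    stop("lesion_delta must be <= 0: ischemic change is hypodense")
  }
  structure(list(image_size = as.integer(image_size),
                 brain_axes = as.numeric(brain_axes),
                 tissue_mean = tissue_mean,
                 tissue_noise_sd = tissue_noise_sd,
                 skull_hu = skull_hu, air_hu = air_hu,
                 lesion_regions = as.integer(lesion_regions),
                 lesion_delta = lesion_delta,
                 lesion_fill = lesion_fill,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized elliptic radius breakpoints of the nested central structures
# (C innermost, then IC, L, I) and start of the cortical M sectors
.atlas_radii <- c(C = 0.18, IC = 0.28, L = 0.38, I = 0.48)

#' Build the programmatic ASPECTS territory atlas
#'
#' Partitions each hemisphere's brain interior deterministically: on the
#' ganglionic level, nested elliptic annuli host C, IC, L and I (innermost
#' to outermost) and the remaining cortical ribbon splits into three 60
#' degree sectors M1 (anterior) to M3 (posterior); the supraganglionic
#' level splits entirely into sectors M4-M6. Left and right label masks are
#' exact mirror images about the vertical midline. The atlas also carries a
#' clean (noise-free) template volume used as the fixed reference for
#' registration.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `region_atlas` with fields `labels`
#'   (`[N, N, 2]` integer array, 0 = background), `template` (a
#'   [ct_volume()]), `label_table`, `slice_levels` and the generating
#'   geometry.
#' @export
build_template_atlas <- function(spec = phantom_spec()) {
  N <- spec$image_size
  if (N < 64) stop("configuration error: image_size too small to host all regions")
  a <- spec$brain_axes[1]; b <- spec$brain_axes[2]
  cx <- (N + 1) / 2; cy <- (N + 1) / 2
  x <- matrix(seq_len(N), N, N, byrow = TRUE)  # column index
  y <- matrix(seq_len(N), N, N)                # row index
  xn <- (x - cx) / a
  yn <- (cy - y) / b                           # +y = anterior (up)
  u <- sqrt(xn^2 + yn^2)
  phi <- atan2(abs(xn), yn)                    # 0 = anterior, pi = posterior
  right <- xn > 0
  inbrain <- u < 1 & abs(x - cx) > 1e-9        # odd sizes: midline col = falx

  r <- .atlas_radii
  base <- matrix(0L, N, N)
  # cortical sectors (shared angular bands for both levels)
  sect <- ifelse(phi < pi / 3, 1L, ifelse(phi < 2 * pi / 3, 2L, 3L))

  gang <- base
  gang[inbrain] <- (4L + sect[inbrain])                     # M1..M3 -> 5..7
  gang[inbrain & u < r["I"]]  <- 2L                         # I
  gang[inbrain & u < r["L"]]  <- 4L                         # L
  gang[inbrain & u < r["IC"]] <- 3L                         # IC
  gang[inbrain & u < r["C"]]  <- 1L                         # C

  supra <- base
  supra[inbrain] <- 7L + sect[inbrain]                      # M4..M6 -> 8..10

  lab <- array(0L, c(N, N, 2))
  lab[, , 1] <- gang + ifelse(gang > 0 & right, 10L, 0L)
  lab[, , 2] <- supra + ifelse(supra > 0 & right, 10L, 0L)

  tmpl <- matrix(spec$air_hu, N, N)
  tmpl[u < 1.08] <- spec$skull_hu
  tmpl[u < 1] <- spec$tissue_mean
  # ganglionic level carries internal anatomy (denser deep nuclei, CSF in
  # the frontal horns), mirror-symmetric so the difference channel stays
  # null, but off-centre so an affine registration can identify rotation
  gang_tmpl <- tmpl
  gang_tmpl[u < r["I"]] <- spec$tissue_mean + 5
  vent <- (abs(xn) - 0.13)^2 / 0.05^2 + (yn - 0.28)^2 / 0.22^2 < 1
  gang_tmpl[vent & u < 1] <- 5
  template <- ct_volume(array(c(gang_tmpl, tmpl), c(N, N, 2)),
                        slice_levels = c("ganglionic", "supraganglionic"))

  structure(list(labels = lab,
                 template = template,
                 label_table = aspects_label_table(),
                 slice_levels = c("ganglionic", "supraganglionic"),
                 center = c(cx, cy), axes = c(a, b), radii = r),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("region_atlas: %d x %d, levels: %s; 20 MCA-territory labels\n",
              d[1], d[2], paste(x$slice_levels, collapse = " + ")))
  invisible(x)
}

#' Load a user-supplied ASPECTS label volume
#'
#' Accepts any NIfTI label volume following the shipped label convention
#' (1-10 left C, I, IC, L, M1-M6; 11-20 right) together with a template
#' intensity volume for registration.
#'
#' @param label_path NIfTI file of integer labels 0-20.
#' @param template_path NIfTI file with the template intensity image on the
#'   same grid.
#' @param slice_levels per-slice level annotation (recycled if length 1).
#' @return a `region_atlas`.
#' @export
load_atlas <- function(label_path, template_path, slice_levels = NA) {
  lab <- load_volume(label_path)
  tpl <- load_volume(template_path)
  if (!all(dim(lab$data) == dim(tpl$data))) {
    stop("label and template grids disagree")
  }
  labs <- array(as.integer(round(lab$data)), dim(lab$data))
  if (any(labs < 0 | labs > 20)) stop("labels must be integers in 0..20")
  structure(list(labels = labs, template = tpl,
                 label_table = aspects_label_table(),
                 slice_levels = rep(slice_levels, length.out = dim(labs)[3]),
                 center = (dim(labs)[2:1] + 1) / 2, axes = NULL, radii = NULL),
            class = "region_atlas")
}

#' Simulate a subject volume under a known affine
#'
#' Applies a small random affine (|rotation| <= 10 degrees, |translation|
#' <= 10 px, scale 0.9-1.1, drawn uniformly) to the clean template and adds
#' Gaussian HU noise, returning both the volume and the ground-truth
#' transform — the fixture for registration parameter-recovery tests.
#'
#' @param atlas a `region_atlas`.
#' @param spec a [phantom_spec()].
#' @param seed optional integer; when given, the RNG is seeded so the same
#'   seed yields a bit-identical subject.
#' @param transform optional [affine2d()] overriding the random draw
#'   (identity gives template + noise only).
#' @param noise logical; add Gaussian noise of `spec$tissue_noise_sd` HU.
#' @return list with `volume` (a [ct_volume()]), `transform` (the forward
#'   template-to-subject [affine2d()]).
#' @export
simulate_subject <- function(atlas, spec = phantom_spec(), seed = NULL,
                             transform = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transform)) {
    transform <- affine2d(angle = runif(1, -10, 10),
                          tx = runif(1, -10, 10), ty = runif(1, -10, 10),
                          sx = runif(1, 0.9, 1.1), sy = runif(1, 0.9, 1.1),
                          center = atlas$center)
  }
  d <- dim(atlas$labels)
  dat <- array(0, d)
  for (s in seq_len(d[3])) {
    dat[, , s] <- warp_affine(get_slice(atlas$template, s), transform,
                              background = spec$air_hu)
  }
  if (noise && spec$tissue_noise_sd > 0) {
    dat <- dat + rnorm(length(dat), 0, spec$tissue_noise_sd)
  }
  list(volume = ct_volume(dat, slice_levels = atlas$slice_levels),
       transform = transform)
}

# warp the atlas label stack into subject space (nearest neighbour)
warp_labels <- function(atlas, transform) {
  d <- dim(atlas$labels)
  out <- array(0L, d)
  for (s in seq_len(d[3])) {
    out[, , s] <- as.integer(warp_affine(atlas$labels[, , s], transform,
                                         interp = "nearest", background = 0))
  }
  out
}

# smooth random field in [0,1]-ish range: coarse white noise upsampled
# bilinearly; scale controls blob size in pixels
smooth_field <- function(n, scale = 24) {
  cn <- max(4L, as.integer(round(n / scale)))
  coarse <- matrix(rnorm(cn * cn), cn, cn)
  resize_image(coarse, c(n, n))
}

#' Insert a fuzzy hypodense lesion into a phantom case
#'
#' Lowers HU by `spec$lesion_delta` inside a blob grown from thresholded
#' smoothed noise, covering a `spec$lesion_fill` fraction of every target
#' region (per-region quantile thresholding of one shared smooth field, so
#' multi-region lesions stay contiguous). The generative region truth is
#' stored directly: a region is positive iff it is a lesion target.
#'
#' @param case_volume a [ct_volume()] in subject space.
#' @param labels subject-space label array matching the volume grid (use
#'   `atlas$labels` for template-space cases).
#' @param spec a [phantom_spec()] whose `lesion_regions`, `lesion_delta`
#'   and `lesion_fill` define the lesion.
#' @param seed optional RNG seed for the blob field.
#' @return an object of class `phantom_case`: `volume`, `lesion_mask`
#'   (`[N, N, S]` 0/1), `true_scores` (20 binaries), `true_aspects_left`,
#'   `true_aspects_right`, plus the `labels` used.
#' @export
insert_lesion <- function(case_volume, labels, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- spec$lesion_regions
  tab <- aspects_label_table()
  if (length(regions) > 0 && spec$lesion_fill == 0) {
    stop("lesion_fill = 0 with nonempty lesion_regions")
  }
  stopifnot(all(regions %in% tab$label))
  d <- dim(case_volume$data)
  mask <- array(0L, d)
  active <- if (spec$lesion_delta == 0) integer(0) else regions
  if (length(active) > 0 && spec$lesion_fill > 0) {
    for (s in seq_len(d[3])) {
      slice_regions <- intersect(active, labels[, , s])
      if (length(slice_regions) == 0) next
      field <- smooth_field(d[1], scale = d[1] / 5)
      for (k in slice_regions) {
        idx <- which(labels[, , s] == k)
        if (length(idx) == 0) next
        thr <- quantile(field[idx], 1 - spec$lesion_fill, names = FALSE)
        sel <- idx[field[idx] >= thr]
        # quantile ties can overshoot; trim to the requested count
        ntar <- max(1L, round(spec$lesion_fill * length(idx)))
        if (length(sel) > ntar) {
          sel <- idx[order(field[idx], decreasing = TRUE)[seq_len(ntar)]]
        }
        m <- mask[, , s]; m[sel] <- 1L; mask[, , s] <- m
      }
    }
    case_volume$data <- case_volume$data + spec$lesion_delta * mask
  }
  scores <- integer(20)
  scores[active] <- 1L
  structure(list(volume = case_volume, lesion_mask = mask,
                 labels = labels,
                 true_scores = scores,
                 true_aspects_left = 10L - sum(scores[1:10]),
                 true_aspects_right = 10L - sum(scores[11:20])),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case: ASPECTS L %d / R %d, lesion %d px\n",
              x$true_aspects_left, x$true_aspects_right, sum(x$lesion_mask)))
  invisible(x)
}

#' Generate a reproducible phantom cohort
#'
#' Each case draws 20 independent Bernoulli(`prevalence`) region outcomes,
#' simulates a subject (optionally under a random affine), and inserts one
#' lesion per affected hemisphere covering the positive regions. The same
#' seed yields an identical cohort and manifest.
#'
#' @param n number of cases.
#' @param prevalence per-region positive rate in `[0, 1]`.
#' @param spec a [phantom_spec()].
#' @param seed integer master seed.
#' @param random_affine simulate subjects under random affines (`TRUE`) or
#'   on the template grid (`FALSE`).
#' @param atlas optional prebuilt atlas for `spec` (rebuilt if missing).
#' @return list with `cases` (list of `phantom_case`, each also carrying
#'   `case_id` and `transform`), `atlas`, and `manifest` (long data.frame
#'   `case_id`, `region_label`, `region_name`, `side`, `true_score`).
#' @export
generate_cohort <- function(n, prevalence = 0.1, spec = phantom_spec(),
                            seed = spec$seed, random_affine = TRUE,
                            atlas = NULL) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1)
  if (is.null(atlas)) atlas <- build_template_atlas(spec)
  set.seed(seed)
  tab <- aspects_label_table()
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- which(rbinom(20, 1, prevalence) == 1)
    tf <- if (random_affine) NULL else affine2d(center = atlas$center)
    subj <- simulate_subject(atlas, spec, transform = tf)
    labs <- warp_labels(atlas, subj$transform)
    cspec <- spec
    cspec$lesion_regions <- pos
    cs <- insert_lesion(subj$volume, labs, cspec)
    cs$case_id <- sprintf("case_%04d", i)
    cs$transform <- subj$transform
    cases[[i]] <- cs
    rows[[i]] <- data.frame(case_id = cs$case_id,
                            region_label = tab$label,
                            region_name = tab$name,
                            side = tab$side,
                            true_score = cs$true_scores,
                            stringsAsFactors = FALSE)
  }
  list(cases = cases, atlas = atlas, manifest = do.call(rbind, rows))
}
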