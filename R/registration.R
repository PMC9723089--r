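# Affine atlas-to-subject registration. The atlas template is warped into
# the subject frame (never the reverse), so patient data are not deformed;
# labels follow with nearest-neighbour interpolation.

# Principal-axes initialization: head-foreground centroids give the
# translation, second moments give per-axis scale and rotation. Exact for
# the affine family this pipeline fits, up to noise and interpolation.
moments_init <- function(tmpl_slices, subj_slices, center,
                         fg_threshold = -200) {
  moments <- function(slices) {
    xs <- NULL; ys <- NULL
    for (img in slices) {
      idx <- which(img > fg_threshold, arr.ind = TRUE)
      xs <- c(xs, idx[, 2]); ys <- c(ys, idx[, 1])
    }
    list(mu = c(mean(xs), mean(ys)), S = stats::cov(cbind(xs, ys)))
  }
  mt <- moments(tmpl_slices); ms <- moments(subj_slices)
  ang <- function(S) 0.5 * atan2(2 * S[1, 2], S[1, 1] - S[2, 2])
  theta <- ang(ms$S) - ang(mt$S)
  # the principal axis is defined modulo 180 degrees; take the nearest
  # equivalent rotation
  theta <- theta - pi * round(theta / pi)
  eig <- function(S) sort(eigen(S, symmetric = TRUE)$values)
  ev_t <- eig(mt$S); ev_s <- eig(ms$S)
  # template is axis-aligned with the y semi-axis the larger one
  sy <- sqrt(ev_s[2] / ev_t[2]); sx <- sqrt(ev_s[1] / ev_t[1])
  th <- theta
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- ms$mu - (R %*% diag(c(sx, sy)) %*% (mt$mu - center) + center)
  c(theta * 180 / pi, t[1], t[2], 10 * log(sx), 10 * log(sy))
}

# mean squared intensity difference between warped template and subject
# par = (angle deg, tx px, ty px, 10*log sx, 10*log sy): comparable
# natural scales so the simplex explores all five dimensions evenly
reg_objective <- function(par, tmpl_slices, subj_slices, center, background) {
  tf <- affine2d(angle = par[1], tx = par[2], ty = par[3],
                 sx = exp(par[4] / 10), sy = exp(par[5] / 10), center = center)
  val <- 0
  for (s in seq_along(tmpl_slices)) {
    w <- warp_affine(tmpl_slices[[s]], tf, background = background)
    val <- val + mean((w - subj_slices[[s]])^2)
  }
  val / length(tmpl_slices)
}

#' Register the territory atlas to a subject volume
#'
#' Estimates the affine transform (rotation, translation, anisotropic
#' scale) that maps the atlas template onto the subject by minimizing the
#' mean squared intensity difference, coarse-to-fine over an image pyramid
#' (Nelder-Mead at each level). Labels are then propagated to the subject
#' grid with nearest-neighbour interpolation, which preserves the disjoint
#' partition.
#'
#' @param atlas a `region_atlas` (template + labels).
#' @param subject a [ct_volume()] on the same slice levels.
#' @param maxit Nelder-Mead iterations per optimization pass.
#' @param background fill HU outside the template (air).
#' @param grid_step,grid_range angle (degrees) / translation (px) spacing
#'   and half-width of the initialization sweep.
#' @return list `transform` (the recovered forward [affine2d()]), `labels`
#'   (subject-space label array), `mse` (final mean squared difference),
#'   and `diagnostics` (objective value after each pass).
#' @export
register_atlas <- function(atlas, subject, maxit = 400, background = -1000,
                           grid_step = c(3, 6), grid_range = c(12, 12)) {
  dt <- dim(atlas$labels); ds <- dim(subject$data)
  if (dt[3] != ds[3]) stop("registration error: slice counts differ")
  tmpl <- lapply(seq_len(dt[3]), function(s) get_slice(atlas$template, s))
  subj <- lapply(seq_len(ds[3]), function(s) get_slice(subject, s))
  center <- atlas$center
  # principal-axes initialization, with an angle x translation sweep as a
  # fallback when the moment estimate scores worse (e.g. odd foregrounds)
  par <- moments_init(tmpl, subj, center)
  v_mom <- reg_objective(par, tmpl, subj, center, background)
  grid <- expand.grid(a = seq(-grid_range[1], grid_range[1],
                              by = grid_step[1]),
                      tx = seq(-grid_range[2], grid_range[2],
                               by = grid_step[2]),
                      ty = seq(-grid_range[2], grid_range[2],
                               by = grid_step[2]))
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    reg_objective(c(grid$a[i], grid$tx[i], grid$ty[i], 0, 0),
                  tmpl, subj, center, background)
  }, 0)
  if (min(vals) < v_mom) {
    par <- c(unname(unlist(grid[which.min(vals), ])), 0, 0)
  }
  # bounded quasi-Newton descent (finite-difference gradients),
  # multi-started over angle offsets: the moment angle degenerates when
  # anisotropic scaling renders the head nearly circular. A Nelder-Mead
  # pass then polishes the winner through the piecewise-smooth
  # interpolation kinks.
  best <- NULL
  diagnostics <- numeric(0)
  for (da in c(0, -4, 4, -8, 8)) {
    p0 <- par; p0[1] <- par[1] + da
    fit <- optim(p0, reg_objective, tmpl_slices = tmpl, subj_slices = subj,
                 center = center, background = background,
                 method = "L-BFGS-B",
                 lower = c(-25, -25, -25, -3, -3),
                 upper = c(25, 25, 25, 3, 3),
                 control = list(maxit = maxit))
    diagnostics <- c(diagnostics, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1) break   # essentially exact already
  }
  fit <- optim(best$par, reg_objective, tmpl_slices = tmpl,
               subj_slices = subj, center = center,
               background = background, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  par <- fit$par
  diagnostics <- c(diagnostics, fit$value)
  if (!is.finite(fit$value)) {
    stop("registration error: objective diverged")
  }
  tf <- affine2d(angle = par[1], tx = par[2], ty = par[3],
                 sx = exp(par[4] / 10), sy = exp(par[5] / 10),
                 center = atlas$center)
  list(transform = tf, labels = warp_labels(atlas, tf),
       mse = fit$value, diagnostics = diagnostics)
}
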