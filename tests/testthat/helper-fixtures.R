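# Shared fixtures: a scaled-down model configuration (small canvas, two
# scales, eight orientations) keeps the layer tests fast while preserving
# every structural property of the full default model.

small_config <- function(...) {
  base <- list(
    canvas = c(160L, 160L),
    orientations = 8L,
    sizes = c(20, 40),
    aspect_ratios = c(1, 2),
    sigma_l = c(10, 20),
    sigma_w = c(7, 7),
    gain_flank = c(1.5, 1.5),
    degree_displacement = c(0.5, 0.5),
    sign_displacement = c(0.25, 0.25),
    radial_bin = 10,
    angular_bin = pi / 9,
    max_radius = 70
  )
  do.call(model_config, utils::modifyList(base, list(...)))
}

# arc bulging toward +x (side = 1) or -x (side = -1), apex at the canvas
# center, vertical tangent there
side_arc <- function(radius, side = 1, canvas = c(160L, 160L),
                     extent = pi, smooth = TRUE) {
  ctr <- shapecurv:::canvas_center(canvas)
  render_arc(radius, center = c(ctr[1] + side * radius, ctr[2]),
             angular_extent = extent,
             orientation = if (side > 0) pi else 0,
             canvas = canvas, smooth = smooth)
}

# principal-axis orientation of the foreground pixels via image moments
# (independent oracle for renderer orientation)
moments_orientation <- function(image) {
  px <- pixel_coords(image)
  x <- px$x - mean(px$x)
  yup <- -(px$y - mean(px$y))
  cov <- matrix(c(mean(x^2), mean(x * yup), mean(x * yup), mean(yup^2)), 2)
  v <- eigen(cov)$vectors[, 1]
  atan2(v[2], v[1]) %% pi
}

# algebraic least-squares circle fit (Kasa), an oracle for arc radii
circle_fit <- function(image) {
  px <- pixel_coords(image)
  fit <- stats::lm(I(x^2 + y^2) ~ x + y, data = px)
  cx <- stats::coef(fit)[["x"]] / 2
  cy <- stats::coef(fit)[["y"]] / 2
  r <- sqrt(stats::coef(fit)[["(Intercept)"]] + cx^2 + cy^2)
  list(center = c(cx, cy), radius = r)
}

# number of modes of a tuning curve after light smoothing: a secondary
# local maximum counts as a separate mode only if the valley between it
# and the global peak dips more than `ripple` (fraction of max) below it
count_modes <- function(resp, ripple = 0.05) {
  if (length(resp) < 3) return(1L)
  sm <- stats::filter(resp, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- resp[is.na(sm)]
  v <- as.numeric(sm)
  v <- v[c(TRUE, diff(v) != 0)]        # collapse plateaus
  v <- v / max(v)
  if (length(v) < 3) return(1L)
  g <- which.max(v)
  peaks <- which(diff(sign(diff(c(-Inf, v, -Inf)))) < 0)
  extra <- 0L
  for (p in peaks) {
    if (p == g) next
    sep <- if (p < g) min(v[p:g]) else min(v[g:p])
    if (v[p] - sep > ripple) extra <- extra + 1L
  }
  1L + extra
}
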