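#' Saturating output nonlinearity
#'
#' A logistic saturation re-anchored so that zero input maps to zero
#' output: `g(x) = (L(x) - L(0)) / (1 - L(0))` with
#' `L(x) = 1 / (1 + exp(-alpha * (x - beta)))`. `g` is monotone
#' non-decreasing, `g(0) = 0`, and `g` tends to 1 for intense stimuli;
#' for small `alpha * beta` it is close to linear, so it only reshapes
#' responses to strongly driving inputs. The half-saturation `beta` is
#' set per scale to the maximum response of that scale's endstopped set
#' divided by `sigmoid_beta_divisor`.
#'
#' @param x Non-negative input (number, vector or matrix).
#' @param alpha Slope parameter.
#' @param beta Half-saturation point.
#' @return Saturated values, same shape as `x`.
#' @export
response_sigmoid <- function(x, alpha, beta) {
  if (beta <= 0) return(x * 0)
  l0 <- 1 / (1 + exp(alpha * beta))
  (1 / (1 + exp(-alpha * (x - beta))) - l0) / (1 - l0)
}

# displaced complex-cell sample: the flanker centered at p + d has its
# response looked up at that displaced location
flanker_sample <- function(map, d, dir) {
  shift_image(map, d * dir[1], d * dir[2])
}

#' Endstopped responses (degree and sign of curvature)
#'
#' Both endstopped operators subtract two displaced inhibitory complex
#' cells from one excitatory simple cell:
#'
#' * Degree cells use flankers of the *same* orientation as the center,
#'   displaced along the preferred orientation by a per-scale fraction of
#'   the cell size. Contours that stay inside the central receptive field
#'   (high curvature for small cells, broad curvature for large ones)
#'   excite without touching the flankers; straighter contours run into
#'   the inhibitory flankers.
#' * Sign cells use flankers rotated +-45 degrees, placed obliquely on one
#'   side of the center; the two sign variants swap the flanker placement,
#'   so a curve bending one way passes only through the excitatory center
#'   while its mirror image lands on the inhibitory flankers.
#'
#' The rectified difference is passed through [response_sigmoid()] with a
#' per-scale half-saturation (the scale's maximum raw response over this
#' image divided by `sigmoid_beta_divisor`).
#'
#' @param simple,complex Response stacks from [simple_responses()] and
#'   [complex_responses()] (same configuration and scales).
#' @param apply_sigmoid Apply the saturating nonlinearity (default TRUE).
#' @return A list of response stacks `degree`, `sign_pos`, `sign_neg`.
#' @export
endstopped_responses <- function(simple, complex, apply_sigmoid = TRUE) {
  stopifnot(inherits(simple, "response_stack"),
            inherits(complex, "response_stack"),
            identical(attr(simple, "scales"), attr(complex, "scales")))
  config <- attr(simple, "config")
  scales <- attr(simple, "scales")
  n_o <- config$orientations
  angles <- orientation_angles(config)
  if (n_o %% 4 != 0) {
    stop("sign-of-curvature cells need orientation channels at +-45 ",
         "degrees: use a multiple of 4 orientations", call. = FALSE)
  }
  off45 <- n_o / 4L
  deg <- array(0, dim(simple))
  pos <- array(0, dim(simple))
  neg <- array(0, dim(simple))
  # straight-contour evidence: the raw degree response of each location's
  # dominant simple channel (used by the local-curvature layer)
  best_s <- matrix(-Inf, dim(simple)[1], dim(simple)[2])
  best_e <- matrix(0, dim(simple)[1], dim(simple)[2])
  cc <- config$gain_center
  for (si in seq_along(scales)) {
    s <- scales[si]
    size <- config$sizes[s]
    cf <- config$gain_flank[s]
    d_deg <- config$degree_displacement[s] * size
    d_sgn <- config$sign_displacement[s] * size
    for (oi in seq_len(n_o)) {
      th <- angles[oi]
      s_map <- simple[, , oi, si]
      c_map <- complex[, , oi, si]
      u <- angle_dir(th)
      e_raw <- endstop_combine(
        s_map,
        flanker_sample(c_map, +d_deg, u),
        flanker_sample(c_map, -d_deg, u),
        cc, cf
      )
      deg[, , oi, si] <- e_raw
      upd <- s_map > best_s
      best_s[upd] <- s_map[upd]
      best_e[upd] <- e_raw[upd]
      # oblique flankers: orientation channels at theta +- 45 degrees
      oi_p <- (oi - 1 + off45) %% n_o + 1   # theta + 45
      oi_m <- (oi - 1 - off45) %% n_o + 1   # theta - 45
      c_p <- complex[, , oi_p, si]
      c_m <- complex[, , oi_m, si]
      u_p <- angle_dir(th + pi / 4)
      u_m <- angle_dir(th - pi / 4)
      pos[, , oi, si] <- endstop_combine(
        s_map,
        flanker_sample(c_p, +d_sgn, u_p),
        flanker_sample(c_m, -d_sgn, u_m),
        cc, cf
      )
      neg[, , oi, si] <- endstop_combine(
        s_map,
        flanker_sample(c_p, -d_sgn, u_p),
        flanker_sample(c_m, +d_sgn, u_m),
        cc, cf
      )
    }
  }
  if (apply_sigmoid) {
    for (si in seq_along(scales)) {
      beta <- max(deg[, , , si], pos[, , , si], neg[, , , si]) /
        config$sigmoid_beta_divisor
      deg[, , , si] <- response_sigmoid(deg[, , , si], config$sigmoid_alpha, beta)
      pos[, , , si] <- response_sigmoid(pos[, , , si], config$sigmoid_alpha, beta)
      neg[, , , si] <- response_sigmoid(neg[, , , si], config$sigmoid_alpha, beta)
    }
  }
  best_s[!is.finite(best_s)] <- 0
  list(degree = new_response_stack(deg, config, scales, "endstopped_degree"),
       sign_pos = new_response_stack(pos, config, scales, "endstopped_sign_pos"),
       sign_neg = new_response_stack(neg, config, scales, "endstopped_sign_neg"),
       straight_stats = list(best_simple = best_s, best_degree_raw = best_e))
}

#' Single-channel endstopped responses
#'
#' Convenience accessors for one (scale, orientation) channel of the
#' degree-of-curvature or sign-of-curvature operators.
#'
#' @inheritParams endstopped_responses
#' @param scale Scale index (1-based, must be present in the stacks).
#' @param orientation_index Orientation channel (1-based).
#' @param sign `"positive"` or `"negative"` variant.
#' @return A response matrix.
#' @export
degree_response <- function(simple, complex, scale, orientation_index,
                            apply_sigmoid = TRUE) {
  es <- endstopped_responses(simple, complex, apply_sigmoid = apply_sigmoid)
  stack_channel(es$degree, scale, orientation_index)
}

#' @rdname degree_response
#' @export
sign_response <- function(simple, complex, scale, orientation_index,
                          sign = c("positive", "negative"),
                          apply_sigmoid = TRUE) {
  sign <- match.arg(sign)
  es <- endstopped_responses(simple, complex, apply_sigmoid = apply_sigmoid)
  stack <- if (sign == "positive") es$sign_pos else es$sign_neg
  stack_channel(stack, scale, orientation_index)
}

# ---- curvature tuning --------------------------------------------------

# Arc stimulus of the tuning sweep: the circle of the requested radius
# passes through the canvas center with a vertical tangent there (circle
# center displaced +radius along x). Extent is half a turn, clipped so the
# arc stays `margin` px inside the canvas.
tuning_arc <- function(radius, canvas = c(400L, 400L), margin = 30,
                       smooth = TRUE) {
  ctr <- canvas_center(canvas)
  lim <- min(ctr[1], ctr[2]) - margin
  h1 <- if (radius <= lim) pi else asin(min(1, lim / radius))
  h2 <- if (2 * radius <= lim) pi else acos(max(-1, 1 - lim / radius))
  half <- min(h1, h2, pi / 2)
  render_arc(radius, center = c(ctr[1] + radius, ctr[2]),
             angular_extent = 2 * half, orientation = pi,
             canvas = canvas, smooth = smooth)
}

# kernel value lookup at continuous offsets (bilinear, zero outside)
kernel_lookup <- function(k, dx, dy) {
  h <- (nrow(k) - 1) / 2
  ix <- dx + h + 1; iy <- dy + h + 1
  fx <- floor(ix); fy <- floor(iy)
  ax <- ix - fx; ay <- iy - fy
  val <- function(r, c) {
    ok <- r >= 1 & r <= nrow(k) & c >= 1 & c <= ncol(k)
    out <- numeric(length(r))
    out[ok] <- k[cbind(r[ok], c[ok])]
    out
  }
  (1 - ax) * (1 - ay) * val(fy, fx) + ax * (1 - ay) * val(fy, fx + 1) +
    (1 - ax) * ay * val(fy + 1, fx) + ax * ay * val(fy + 1, fx + 1)
}

# degree-of-curvature endstopped response of a single probe cell at `q`
# (continuous 0-based point) with vertical preferred orientation, computed
# directly from the contour pixel list (columns x, y, value)
probe_degree_response <- function(px, q, kernel, config, scale) {
  spacing <- config$pool_spacing * config$sigma_w[scale]
  w <- pool_weights(config$pool_subunits)
  ks <- seq_len(config$pool_subunits) - (config$pool_subunits + 1) / 2
  tvec <- angle_dir(pi / 2)          # along the preferred orientation
  nvec <- angle_dir(pi)              # perpendicular
  s_at <- function(p) {
    max(0, sum(px$value * kernel_lookup(kernel, px$x - p[1], px$y - p[2])))
  }
  c_at <- function(p) {
    acc <- 0
    for (j in seq_along(ks)) {
      acc <- acc + w[j] * s_at(p + ks[j] * spacing * nvec)
    }
    acc
  }
  d <- config$degree_displacement[scale] * config$sizes[scale]
  cf <- config$gain_flank[scale]
  max(0, config$gain_center * s_at(q) -
        cf * c_at(q + d * tvec) - cf * c_at(q - d * tvec))
}

#' Curvature tuning curve of a degree-of-curvature endstopped cell
#'
#' Sweeps arcs of the given radii past one model endstopped cell and
#' records its response per radius, normalized to `[0, 1]` over the sweep.
#' The default (`pool = "probe"`) fixes the cell at the arc apex with its
#' preferred orientation matched to the tangent there, probing the same
#' cell with every stimulus; arcs are anti-aliased half-turns through the
#' probe point. `pool = "image"` instead runs the full response maps and
#' takes the maximum over orientation channels and contour pixels (slower
#' and noisier; retained for cross-checks).
#'
#' @param scale Scale index of the endstopped cell.
#' @param radii Arc radii to sweep, px (> 0).
#' @param config An [model_config()].
#' @param pool `"probe"` (fixed apex cell) or `"image"` (max over contour
#'   and orientations).
#' @param smooth Anti-alias the arc stimuli (recommended).
#' @return A tibble of class `sc_tuning` with columns `radius`, `response`
#'   (raw) and `response_norm`; the scale and the 90%-of-max radius band
#'   are attached as attributes `scale` and `band`.
#' @examples
#' cfg <- model_config()
#' curve <- curvature_tuning_curve(1, seq(4, 20, 2), cfg)
#' attr(curve, "band")
#' @export
curvature_tuning_curve <- function(scale, radii, config = model_config(),
                                   pool = c("probe", "image"),
                                   smooth = TRUE) {
  pool <- match.arg(pool)
  if (length(radii) == 0) stop("`radii` must be non-empty", call. = FALSE)
  if (any(radii <= 0)) stop("arc radii must be > 0", call. = FALSE)
  stopifnot(scale %in% seq_len(n_scales(config)))
  canvas <- config$canvas
  if (pool == "probe") {
    kernel <- dog_kernel(config$sizes[scale], config$sigma_l[scale],
                         config$sigma_w[scale], config$width_ratio, pi / 2)
    q <- canvas_center(canvas)
    resp <- vapply(radii, function(r) {
      img <- tuning_arc(r, canvas, smooth = smooth)
      probe_degree_response(pixel_coords(img), q, kernel, config, scale)
    }, numeric(1))
  } else {
    bank <- prepare_filter_bank(config, scales = scale)
    resp <- vapply(radii, function(r) {
      img <- tuning_arc(r, canvas, smooth = smooth)
      simple <- simple_responses(img, config, bank = bank)
      cx <- complex_responses(simple)
      es <- endstopped_responses(simple, cx, apply_sigmoid = FALSE)
      pooled <- apply(es$degree[, , , 1, drop = FALSE], c(1, 2), max)
      max(pooled[unclass(img) > 0])
    }, numeric(1))
  }
  mx <- max(resp)
  out <- tibble::tibble(radius = as.numeric(radii), response = resp,
                        response_norm = if (mx > 0) resp / mx else resp * 0)
  out <- structure(out, class = c("sc_tuning", class(tibble::tibble())),
                   scale = scale)
  attr(out, "band") <- tryCatch(band_90pct(out), error = function(e) NULL)
  out
}

#' 90%-of-maximum response band
#'
#' The radius interval over which a tuning curve stays at or above 90% of
#' its maximum: the smallest and largest such radius, with linear
#' interpolation between sampled radii at the crossings.
#'
#' @param curve An `sc_tuning` tibble, or anything with columns `radius`
#'   and `response`.
#' @param threshold Band level as a fraction of the maximum (default 0.9).
#' @return Named numeric `c(low, high)` in px.
#' @export
band_90pct <- function(curve, threshold = 0.9) {
  radius <- curve$radius
  resp <- curve$response
  if (length(radius) == 0) stop("empty tuning curve", call. = FALSE)
  if (max(resp) <= 0) {
    stop("tuning curve is identically zero; no band exists", call. = FALSE)
  }
  ord <- order(radius)
  radius <- radius[ord]; resp <- resp[ord]
  thr <- threshold * max(resp)
  above <- which(resp >= thr)
  i <- min(above); j <- max(above)
  low <- radius[i]
  if (i > 1) {
    low <- radius[i - 1] + (thr - resp[i - 1]) *
      (radius[i] - radius[i - 1]) / (resp[i] - resp[i - 1])
  }
  high <- radius[j]
  if (j < length(radius)) {
    high <- radius[j] + (thr - resp[j]) *
      (radius[j + 1] - radius[j]) / (resp[j + 1] - resp[j])
  }
  c(low = low, high = high)
}
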