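#' Oriented difference-of-Gaussians kernel
#'
#' The simple-cell receptive field is the difference of two concentric 2-D
#' Gaussians sharing an elongation `sigma_l` along the preferred
#' orientation and differing across it: the narrow component has width
#' `sigma_w`, the broad (subtracted) component `width_ratio * sigma_w`.
#' This produces an excitatory ridge along the orientation flanked by
#' inhibitory side lobes, an even-symmetric line detector for white
#' contours on black. The kernel is truncated to a `size x size` support,
#' then made zero-mean (so uniform images give no response) and
#' L2-normalized (so responses are comparable across scales).
#'
#' @param size Support in px; rounded to the nearest odd integer.
#' @param sigma_l Gaussian sd along the orientation, px.
#' @param sigma_w Narrow Gaussian sd across the orientation, px.
#' @param width_ratio Broad-to-narrow width ratio (> 1).
#' @param orientation Preferred orientation, radians in `[0, pi)`.
#' @return A numeric `size x size` matrix summing to 0 with unit L2 norm.
#' @examples
#' k <- dog_kernel(41, sigma_l = 20, sigma_w = 10, orientation = pi / 2)
#' abs(sum(k)) < 1e-10
#' @export
dog_kernel <- function(size, sigma_l, sigma_w, width_ratio = 2.5,
                       orientation = 0) {
  if (size < 3) stop("kernel support must be at least 3 px", call. = FALSE)
  stopifnot(sigma_l > 0, sigma_w > 0, width_ratio > 1)
  s <- 2L * floor(size / 2) + 1L
  half <- (s - 1) / 2
  xs <- seq(-half, half)
  x <- matrix(xs, s, s, byrow = TRUE)
  yup <- -matrix(xs, s, s)        # y axis flipped: angles ccw from +x
  u <- x * cos(orientation) + yup * sin(orientation)
  v <- -x * sin(orientation) + yup * cos(orientation)
  g <- function(sw) {
    exp(-u^2 / (2 * sigma_l^2) - v^2 / (2 * sw^2)) / (2 * pi * sigma_l * sw)
  }
  k <- g(sigma_w) - g(width_ratio * sigma_w)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' The simple-cell filter bank
#'
#' One oriented DoG per (orientation, scale) pair; 12 orientations by 4
#' sizes = 48 members under the default configuration.
#'
#' @param config An [model_config()].
#' @return A tibble with one row per bank member: `scale`, `size`,
#'   `orientation_index`, `orientation`, `sigma_l`, `sigma_w`,
#'   `aspect_ratio`, `width_ratio`.
#' @export
filter_bank <- function(config = model_config()) {
  stopifnot(inherits(config, "sc_config"))
  angles <- orientation_angles(config)
  tidyr::expand_grid(
    scale = seq_len(n_scales(config)),
    orientation_index = seq_len(config$orientations)
  ) |>
    dplyr::mutate(
      size = config$sizes[.data$scale],
      orientation = angles[.data$orientation_index],
      sigma_l = config$sigma_l[.data$scale],
      sigma_w = config$sigma_w[.data$scale],
      aspect_ratio = config$aspect_ratios[.data$scale],
      width_ratio = config$width_ratio
    )
}

#' @rdname filter_bank
#' @param x A `filter_bank()` row (or any list with `size`, `sigma_l`,
#'   `sigma_w`, `width_ratio`, `orientation`).
#' @return `bank_kernel()`: the kernel matrix for one bank member.
#' @export
bank_kernel <- function(x) {
  dog_kernel(x$size, x$sigma_l, x$sigma_w, x$width_ratio, x$orientation)
}

# ---- FFT convolution with cached kernel transforms ---------------------

pad_dim <- function(n, k) stats::nextn(n + k - 1, c(2, 3, 5))

# precompute the padded FFT of one kernel
conv_prep <- function(kernel, canvas) {
  kd <- dim(kernel)
  py <- pad_dim(canvas[1], kd[1])
  px <- pad_dim(canvas[2], kd[2])
  km <- matrix(0, py, px)
  km[seq_len(kd[1]), seq_len(kd[2])] <- kernel
  list(fft = stats::fft(km), py = py, px = px, ky = kd[1], kx = kd[2])
}

conv_image_fft <- function(image, py, px) {
  m <- matrix(0, py, px)
  m[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  stats::fft(m)
}

# 'same'-size zero-padded convolution given precomputed transforms
conv_apply <- function(image_fft, prep, canvas) {
  out <- Re(stats::fft(image_fft * prep$fft, inverse = TRUE)) /
    (prep$py * prep$px)
  oy <- (prep$ky - 1) / 2
  ox <- (prep$kx - 1) / 2
  out[seq_len(canvas[1]) + oy, seq_len(canvas[2]) + ox]
}

#' Precompute filter transforms for repeated use
#'
#' Caches the padded Fourier transform of every bank kernel so that
#' sweeps over many stimuli (tuning curves, batteries) pay the kernel
#' cost once.
#'
#' @param config An [model_config()].
#' @param scales Which scales to prepare (default all).
#' @return An opaque `sc_bank` object accepted by [simple_responses()].
#' @export
prepare_filter_bank <- function(config = model_config(), scales = NULL) {
  stopifnot(inherits(config, "sc_config"))
  if (is.null(scales)) scales <- seq_len(n_scales(config))
  angles <- orientation_angles(config)
  canvas <- config$canvas
  preps <- lapply(scales, function(s) {
    lapply(angles, function(a) {
      conv_prep(dog_kernel(config$sizes[s], config$sigma_l[s],
                           config$sigma_w[s], config$width_ratio, a),
                canvas)
    })
  })
  structure(list(preps = preps, scales = scales, config = config),
            class = "sc_bank")
}

# ---- response stacks ---------------------------------------------------

# stacks are arrays [y, x, orientation, scale-slot] with the scale ids in
# attr "scales"; all user-facing docs describe the logical indexing
new_response_stack <- function(values, config, scales, layer) {
  structure(values, config = config, scales = scales, layer = layer,
            class = c("response_stack", "array"))
}

#' @export
print.response_stack <- function(x, ...) {
  d <- dim(x)
  cat("<response_stack:", attr(x, "layer"), "> ",
      d[1], "x", d[2], " px, ", d[3], " orientations, ",
      d[4], " scale(s); max ", signif(max(x), 4), "\n", sep = "")
  invisible(x)
}

#' Extract one channel of a response stack
#'
#' @param stack A response stack.
#' @param scale Scale identifier (as in the model config, 1-based).
#' @param orientation_index Orientation channel, 1-based.
#' @return The response matrix of that channel.
#' @export
stack_channel <- function(stack, scale, orientation_index) {
  slot <- match(scale, attr(stack, "scales"))
  if (is.na(slot)) {
    stop("scale ", scale, " is not present in this stack", call. = FALSE)
  }
  stack[, , orientation_index, slot]
}

relu <- function(m) {
  m[m < 0] <- 0
  m
}

#' Simple-cell responses
#'
#' Rectified convolution of the stimulus with every filter-bank member.
#' Border policy: zero padding, 'same' output size (stimuli are black-
#' padded contours, so the border is neutral).
#'
#' @param image A [stimulus_image()] (or matrix in `[0, 1]`).
#' @param config An [model_config()].
#' @param bank Optional [prepare_filter_bank()] result for repeated calls.
#' @param scales Which scales to compute (default: all, or the bank's).
#' @return A response stack of dimension (height, width, orientations,
#'   scales), all values >= 0.
#' @export
simple_responses <- function(image, config = model_config(), bank = NULL,
                             scales = NULL) {
  image <- as_stimulus_image(image, canvas = config$canvas)
  if (is.null(bank)) {
    if (is.null(scales)) scales <- seq_len(n_scales(config))
    bank <- prepare_filter_bank(config, scales)
  } else {
    stopifnot(inherits(bank, "sc_bank"))
    scales <- bank$scales
  }
  canvas <- config$canvas
  n_o <- config$orientations
  out <- array(0, c(canvas[1], canvas[2], n_o, length(scales)))
  # one padded image transform per distinct pad geometry
  fft_cache <- list()
  for (si in seq_along(scales)) {
    for (oi in seq_len(n_o)) {
      prep <- bank$preps[[si]][[oi]]
      key <- paste(prep$py, prep$px)
      if (is.null(fft_cache[[key]])) {
        fft_cache[[key]] <- conv_image_fft(image, prep$py, prep$px)
      }
      out[, , oi, si] <- relu(conv_apply(fft_cache[[key]], prep, canvas))
    }
  }
  new_response_stack(out, config, scales, "simple")
}

# bilinear sample of m at (x + dx, y + dy); zero outside the image
# (compiled; shift_image_ref is the pure-R reference used in tests)
shift_image <- function(m, dx, dy) {
  shift_bilinear(m, dx, dy)
}

shift_image_ref <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  fx <- floor(dx); fy <- floor(dy)
  ax <- dx - fx; ay <- dy - fy
  grab <- function(ix, iy) {
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny) + iy; xs <- seq_len(nx) + ix
    vy <- ys >= 1 & ys <= ny; vx <- xs >= 1 & xs <= nx
    out[vy, vx] <- m[ys[vy], xs[vx]]
    out
  }
  out <- (1 - ax) * (1 - ay) * grab(fx, fy)
  if (ax > 0) out <- out + ax * (1 - ay) * grab(fx + 1, fy)
  if (ay > 0) out <- out + (1 - ax) * ay * grab(fx, fy + 1)
  if (ax > 0 && ay > 0) out <- out + ax * ay * grab(fx + 1, fy + 1)
  out
}

# Gaussian subunit weights of the complex pooling stage, normalized to 1
pool_weights <- function(n) {
  k <- seq_len(n) - (n + 1) / 2
  w <- exp(-k^2 / 2)
  w / sum(w)
}

# unit vector of angle a in (x, y-down) pixel coordinates
angle_dir <- function(a) c(cos(a), -sin(a))

#' Complex-cell responses
#'
#' Each complex cell is the normalized Gaussian-weighted sum of five
#' simple cells of the same orientation, laterally displaced perpendicular
#' to the preferred orientation (spacing `pool_spacing * sigma_w`).
#' Displacements are continuous and sampled bilinearly. The result is
#' orientation selective but more position tolerant, and spatially
#' broader across the contour, than the simple map.
#'
#' @param simple A response stack from [simple_responses()].
#' @return A response stack (layer `"complex"`) of the same dimensions.
#' @export
complex_responses <- function(simple) {
  stopifnot(inherits(simple, "response_stack"),
            attr(simple, "layer") == "simple")
  config <- attr(simple, "config")
  scales <- attr(simple, "scales")
  angles <- orientation_angles(config)
  n <- config$pool_subunits
  w <- pool_weights(n)
  ks <- seq_len(n) - (n + 1) / 2
  out <- array(0, dim(simple))
  for (si in seq_along(scales)) {
    spacing <- config$pool_spacing * config$sigma_w[scales[si]]
    for (oi in seq_len(config$orientations)) {
      perp <- angle_dir(angles[oi] + pi / 2)
      s_map <- simple[, , oi, si]
      out[, , oi, si] <- relu(pool_shifted(s_map, ks * spacing * perp[1],
                                           ks * spacing * perp[2], w))
    }
  }
  new_response_stack(out, config, scales, "complex")
}
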