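#' Polar position bins of the shape layer
#'
#' Shape-selective units encode curvature parts by their polar position
#' relative to an origin: the radial distance and the angular position,
#' discretized into bins of `radial_bin` px by `angular_bin` radians
#' (20 x 90 = 1,800 bins under the defaults).
#'
#' @param point `(x, y)` position (0-based px), or a matrix / data frame
#'   of such positions.
#' @param origin `(x, y)` origin of the polar grid.
#' @param config An [model_config()] carrying the grid parameters.
#' @return A tibble with 0-based integer columns `radial_bin` and
#'   `angular_bin` (one row per point).
#' @examples
#' polar_bin_index(c(205, 200), c(200, 200), model_config())
#' @export
polar_bin_index <- function(point, origin, config = model_config()) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  pts <- as.matrix(point)
  out <- bin_points(pts[, 1], pts[, 2], origin, config)
  if (anyNA(out$radial_bin)) {
    bad <- which(is.na(out$radial_bin))[1]
    stop("point (", pts[bad, 1], ", ", pts[bad, 2], ") lies beyond the ",
         "grid's maximum radius of ", config$max_radius, " px",
         call. = FALSE)
  }
  out
}

# vectorized binning; beyond-max-radius points yield NA bins
bin_points <- function(x, y, origin, config) {
  dx <- x - origin[1]
  dy_up <- -(y - origin[2])
  r <- sqrt(dx^2 + dy_up^2)
  phi <- atan2(dy_up, dx) %% (2 * pi)
  n_ang <- n_angular_bins(config)
  rb <- ifelse(r > config$max_radius, NA_integer_,
               pmin(floor(r / config$radial_bin), n_radial_bins(config) - 1L))
  ab <- as.integer(floor(phi / config$angular_bin)) %% n_ang
  tibble::tibble(radial_bin = as.integer(rb),
                 angular_bin = ifelse(is.na(rb), NA_integer_, ab))
}

#' Representational capacity of the shape code
#'
#' The number of addressable curvature parts: polar position bins times
#' signed curvature classes (1,800 x 8 = 14,400 under the defaults).
#'
#' @param config An [model_config()].
#' @return Integer count.
#' @export
representational_capacity <- function(config = model_config()) {
  n_radial_bins(config) * n_angular_bins(config) * n_curvature_classes(config)
}

# curvature records of a stimulus (image or precomputed map), binned on
# the polar grid around `origin`; out-of-grid pixels are dropped
binned_curvature_records <- function(stimulus, origin, config, bank = NULL) {
  cm <- if (inherits(stimulus, "curvature_map")) stimulus else
    curvature_map(as_stimulus_image(stimulus, config$canvas), config, bank)
  recs <- tidy(cm)
  if (nrow(recs) == 0) return(recs[0, ])
  bins <- bin_points(recs$x, recs$y, origin, config)
  recs$radial_bin <- bins$radial_bin
  recs$angular_bin <- bins$angular_bin
  recs[!is.na(bins$radial_bin), ]
}

resolve_origin <- function(stimulus, origin_mode, config) {
  if (origin_mode == "center") return(canvas_center(config$canvas))
  if (inherits(stimulus, "curvature_map")) {
    recs <- tidy(stimulus)
    if (nrow(recs) == 0) return(canvas_center(config$canvas))
    return(c(mean(recs$x), mean(recs$y)))
  }
  contour_centroid(as_stimulus_image(stimulus))
}

#' Isolate a shape-selective neuron from a template stimulus
#'
#' The neuron's weights are the template's curvature-map responses
#' aggregated into polar (radial x angular) bins per signed curvature
#' class; its normalization constant is set so that the template itself
#' evokes a response of exactly 1.
#'
#' @param template A [stimulus_image()] (or a precomputed
#'   [curvature_map()]).
#' @param config An [model_config()].
#' @param origin `"center"` anchors the polar grid at the canvas center
#'   (the neuron's receptive-field center); `"centroid"` anchors it at the
#'   stimulus centroid.
#' @param bank Optional [prepare_filter_bank()] cache.
#' @return A `shape_neuron` object.
#' @export
isolate_shape_neuron <- function(template, config = model_config(),
                                 origin = c("center", "centroid"),
                                 bank = NULL) {
  origin <- match.arg(origin)
  og <- resolve_origin(template, origin, config)
  recs <- binned_curvature_records(template, og, config, bank)
  if (nrow(recs) == 0) {
    stop("the template produces an empty curvature map; cannot isolate ",
         "a shape neuron from it", call. = FALSE)
  }
  weights <- recs |>
    dplyr::group_by(.data$radial_bin, .data$angular_bin, .data$class,
                    .data$scale, .data$sign) |>
    dplyr::summarise(weight = max(.data$value), .groups = "drop")
  neuron <- structure(
    list(weights = weights, origin_mode = origin, normalization = 1,
         config = config),
    class = "shape_neuron"
  )
  neuron$field <- smoothed_field(weights, config)
  self <- shape_response_raw(neuron, recs)
  if (self <= 0) stop("template self-response is zero", call. = FALSE)
  neuron$normalization <- self
  neuron
}

#' @export
print.shape_neuron <- function(x, ...) {
  cat("<shape_neuron> ", nrow(x$weights), " active curvature parts, ",
      "origin = ", x$origin_mode,
      ", normalization = ", signif(x$normalization, 4), "\n", sep = "")
  invisible(x)
}

# Dense Gaussian-smoothed weight field over the whole polar grid: for
# every (radial bin, angular bin, class) cell, the best-matching template
# part attenuated by polar-position distance (wrap-around angular) and
# curvature-class rank distance; opposite signs never cross-talk.
# Precomputed once per neuron so that probing is a table lookup.
smoothed_field <- function(weights, config) {
  meta <- class_meta(config)
  n_r <- n_radial_bins(config)
  n_a <- n_angular_bins(config)
  n_c <- n_curvature_classes(config)
  field <- array(0, c(n_r, n_a, n_c))
  sig_r <- config$position_sigma[1]
  sig_a <- config$position_sigma[2]
  sig_c <- config$class_sigma
  kr <- min(n_r - 1L, ceiling(4 * sig_r))
  ka <- min((n_a - 1L) %/% 2L, ceiling(4 * sig_a))
  drs <- -kr:kr
  das <- -ka:ka
  g_a <- exp(-das^2 / (2 * sig_a^2))
  for (i in seq_len(nrow(weights))) {
    rb0 <- weights$radial_bin[i]
    ab0 <- weights$angular_bin[i]
    s0 <- weights$scale[i]
    w0 <- weights$weight[i]
    rbs <- rb0 + drs
    ok <- rbs >= 0 & rbs < n_r
    g_r <- exp(-drs[ok]^2 / (2 * sig_r^2))
    cols <- (ab0 + das) %% n_a + 1L
    pos <- outer(w0 * g_r, g_a)            # radial x angular patch
    same <- which(meta$sign == weights$sign[i])
    for (cl in same) {
      g_c <- exp(-(meta$scale[cl] - s0)^2 / (2 * sig_c^2))
      if (g_c < 1e-8) next
      field[rbs[ok] + 1L, cols, cl] <-
        pmax(field[rbs[ok] + 1L, cols, cl], pos * g_c)
    }
  }
  field
}

class_meta <- function(config) {
  n_sc <- n_scales(config)
  tibble::tibble(class = seq_len(2L * n_sc),
                 scale = rep(seq_len(n_sc), each = 2L),
                 sign = rep(c("positive", "negative"), n_sc))
}

neuron_field <- function(neuron) {
  if (!is.null(neuron$field)) return(neuron$field)
  smoothed_field(neuron$weights, neuron$config)
}

# raw (unnormalized) shape response from binned records
shape_response_raw <- function(neuron, recs) {
  if (nrow(recs) == 0) return(0)
  field <- neuron_field(neuron)
  n_r <- dim(field)[1]
  n_a <- dim(field)[2]
  idx <- recs$radial_bin + 1L + n_r * recs$angular_bin +
    n_r * n_a * (recs$class - 1L)
  v <- recs$value * field[idx]
  # max over classes per location, then sum over locations
  loc <- recs$y * 1e6 + recs$x
  ord <- order(loc, -v)
  sum(v[ord][!duplicated(loc[ord])])
}

#' Shape-neuron response to a stimulus
#'
#' Sum over locations of the curvature response weighted by how close
#' each curvature part falls to the neuron's preferred parts, in polar
#' position (Gaussian falloff over bins, wrap-around angular distance)
#' and in curvature class (Gaussian falloff over degree rank; opposite
#' signs evoke nothing). Normalized by the neuron's template response, so
#' the template scores 1; stimuli richer than the template may score
#' slightly above 1 and are reported as-is.
#'
#' @param neuron A [isolate_shape_neuron()] result.
#' @param stimulus A [stimulus_image()] or precomputed [curvature_map()].
#' @param bank Optional [prepare_filter_bank()] cache.
#' @return A scalar response.
#' @export
shape_response <- function(neuron, stimulus, bank = NULL) {
  stopifnot(inherits(neuron, "shape_neuron"))
  cfg <- neuron$config
  og <- resolve_origin(stimulus, neuron$origin_mode, cfg)
  recs <- binned_curvature_records(stimulus, og, cfg, bank)
  shape_response_raw(neuron, recs) / neuron$normalization
}

#' Response profile of a shape neuron over a stimulus battery
#'
#' @param neuron A `shape_neuron`.
#' @param battery A battery tibble (e.g. from [stimulus_battery()]) with a
#'   list-column `image` (and optionally a precomputed list-column
#'   `curvature`), or a plain list of stimulus images.
#' @param bank Optional [prepare_filter_bank()] cache, used when curvature
#'   maps are not precomputed.
#' @return An `sc_profile` tibble with columns `id` and `response`
#'   (normalized by the neuron's template response).
#' @seealso [add_curvature_maps()] to precompute maps shared across
#'   neurons.
#' @export
response_profile <- function(neuron, battery, bank = NULL) {
  battery <- as_battery(battery)
  if (nrow(battery) == 0) stop("empty stimulus battery", call. = FALSE)
  stims <- if ("curvature" %in% names(battery)) battery$curvature else
    battery$image
  resp <- purrr::map_dbl(stims, function(s) shape_response(neuron, s, bank))
  structure(tibble::tibble(id = battery$id, response = resp),
            class = c("sc_profile", class(tibble::tibble())),
            origin_mode = neuron$origin_mode)
}

as_battery <- function(battery) {
  if (inherits(battery, "data.frame")) {
    stopifnot("image" %in% names(battery) || "curvature" %in% names(battery))
    if (!"id" %in% names(battery)) {
      battery$id <- sprintf("stim%03d", seq_len(nrow(battery)))
    }
    return(battery)
  }
  tibble::tibble(id = sprintf("stim%03d", seq_along(battery)),
                 image = as.list(battery))
}

#' Precompute curvature maps for a battery
#'
#' Adds a `curvature` list-column so that several shape neurons can be
#' profiled against the same battery without recomputing the hierarchy.
#'
#' @param battery A battery tibble with an `image` list-column.
#' @param config An [model_config()].
#' @return The battery with a `curvature` list-column appended.
#' @export
add_curvature_maps <- function(battery, config = model_config()) {
  battery <- as_battery(battery)
  bank <- prepare_filter_bank(config)
  battery$curvature <- purrr::map(battery$image, function(img) {
    curvature_map(as_stimulus_image(img, config$canvas), config, bank)
  })
  battery
}

#' @method tidy shape_neuron
#' @export
tidy.shape_neuron <- function(x, ...) x$weights

#' @method glance shape_neuron
#' @export
glance.shape_neuron <- function(x, ...) {
  tibble::tibble(
    n_parts = nrow(x$weights),
    origin_mode = x$origin_mode,
    normalization = x$normalization,
    capacity = representational_capacity(x$config)
  )
}

#' Serialize a shape neuron to JSON
#'
#' Stores the sparse weight table, the polar-grid and model configuration,
#' the origin mode and the normalization constant, so that
#' [read_shape_neuron()] restores a functionally identical neuron.
#'
#' @param neuron A `shape_neuron`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_shape_neuron <- function(neuron, path) {
  stopifnot(inherits(neuron, "shape_neuron"))
  payload <- list(
    weights = as.list(neuron$weights),
    origin_mode = neuron$origin_mode,
    normalization = neuron$normalization,
    config = unclass(neuron$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_neuron
#' @export
read_shape_neuron <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(model_config, payload$config)
  weights <- tibble::as_tibble(payload$weights)
  structure(
    list(weights = weights, origin_mode = payload$origin_mode,
         normalization = payload$normalization, config = config,
         field = smoothed_field(weights, config)),
    class = "shape_neuron"
  )
}
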