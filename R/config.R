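#' Model configuration
#'
#' Builds the full configuration of the shape-representation hierarchy:
#' the oriented difference-of-Gaussians (DoG) filter bank, the complex-cell
#' pooling stage, the endstopped operators for degree and sign of curvature,
#' the straight-contour rule of the local-curvature layer, and the polar
#' binning grid of the shape layer. Defaults are the calibrated study
#' conditions: 12 orientations (0 to 165 degrees in 15 degree steps) at four
#' receptive-field sizes (40, 60, 88 and 120 px), giving a 48-member bank.
#'
#' The per-scale kernel widths `sigma_l` (along the preferred orientation)
#' and `sigma_w` (across it, narrow Gaussian; the broad Gaussian has width
#' `width_ratio * sigma_w`) and the degree-cell flanker displacements were
#' calibrated so that the four degree-of-curvature endstopped cells respond
#' at 90% of their maximum over the radius ranges of roughly 6-11, 25-52,
#' 48-77 and 140-301 px (see the package vignette for the calibration
#' rationale).
#'
#' @param canvas Integer vector of length 2, image height and width in px.
#' @param orientations Number of evenly spaced orientation channels on
#'   `[0, pi)`.
#' @param sizes Receptive-field sizes (filter support) in px, one per scale.
#' @param aspect_ratios Nominal length-to-width aspect ratio per scale
#'   (metadata carried for reference; kernel shape is set by `sigma_l` and
#'   `sigma_w`). Must have one value per size.
#' @param width_ratio Ratio of broad to narrow width Gaussian (> 1).
#' @param sigma_l Length (along-orientation) Gaussian sd per scale, px.
#' @param sigma_w Narrow width (cross-orientation) Gaussian sd per scale, px.
#' @param gain_center Excitatory gain of the central simple cell.
#' @param gain_flank Inhibitory gain of each displaced complex cell, per
#'   scale, applied to both flankers.
#' @param degree_displacement Flanker displacement of the
#'   degree-of-curvature cell, as a fraction of `sizes`, per scale.
#' @param sign_displacement Flanker displacement of the sign-of-curvature
#'   cell, as a fraction of `sizes`, per scale.
#' @param pool_subunits Number of laterally displaced simple cells summed
#'   into a complex cell (odd).
#' @param pool_spacing Subunit spacing as a fraction of `sigma_w`.
#' @param sigmoid_alpha Slope of the saturating output sigmoid.
#' @param sigmoid_beta_divisor Per-scale half-saturation is the maximum
#'   response of that scale's endstopped set divided by this value.
#' @param straight_endstopped A location is flagged straight when the raw
#'   degree-of-curvature response of its dominant orientation channel
#'   falls below this fraction of that channel's simple response.
#' @param straight_simple Fraction of the scene maximum simple response a
#'   location must exceed (i.e. lie on a contour) to be considered by the
#'   straight rule.
#' @param keep_all_scales If `TRUE` (default) every degree scale may
#'   deposit into its curvature class at a location; if `FALSE` only the
#'   winning scale does.
#' @param radial_bin Radial bin size of the shape layer polar grid, px.
#' @param angular_bin Angular bin size of the polar grid, radians.
#' @param max_radius Outer radius of the polar grid, px.
#' @param position_sigma Gaussian position tolerance of shape neurons, in
#'   bins, length 2 (radial, angular).
#' @param class_sigma Gaussian tolerance across curvature-class rank.
#'
#' @return An object of class `sc_config`: a validated named list.
#' @examples
#' cfg <- model_config()
#' nrow(filter_bank(cfg)) # 48
#' @export
model_config <- function(canvas = c(400L, 400L),
                         orientations = 12L,
                         sizes = c(40, 60, 88, 120),
                         aspect_ratios = c(0.7, 1.4, 2.15, 3),
                         width_ratio = 2.5,
                         sigma_l = c(20, 12, 88 / 3, 60),
                         sigma_w = c(10 / 0.7, 6, 22 / 2.15, 10),
                         gain_center = 1,
                         gain_flank = c(1.5, 1.25, 1, 3),
                         degree_displacement = c(0.5, 0.55, 0.5, 1),
                         sign_displacement = c(1 / 5, 1 / 4, 1 / 4, 2 / 5),
                         pool_subunits = 5L,
                         pool_spacing = 0.5,
                         sigmoid_alpha = 0.01,
                         sigmoid_beta_divisor = 8.5,
                         straight_endstopped = 0.1,
                         straight_simple = 0.5,
                         keep_all_scales = TRUE,
                         radial_bin = 10,
                         angular_bin = pi / 45,
                         max_radius = 200,
                         position_sigma = c(1, 1),
                         class_sigma = 1) {
  cfg <- list(
    canvas = as.integer(canvas),
    orientations = as.integer(orientations),
    sizes = as.numeric(sizes),
    aspect_ratios = as.numeric(aspect_ratios),
    width_ratio = width_ratio,
    sigma_l = as.numeric(sigma_l),
    sigma_w = as.numeric(sigma_w),
    gain_center = gain_center,
    gain_flank = as.numeric(gain_flank),
    degree_displacement = as.numeric(degree_displacement),
    sign_displacement = as.numeric(sign_displacement),
    pool_subunits = as.integer(pool_subunits),
    pool_spacing = pool_spacing,
    sigmoid_alpha = sigmoid_alpha,
    sigmoid_beta_divisor = sigmoid_beta_divisor,
    straight_endstopped = straight_endstopped,
    straight_simple = straight_simple,
    keep_all_scales = isTRUE(keep_all_scales),
    radial_bin = radial_bin,
    angular_bin = angular_bin,
    max_radius = max_radius,
    position_sigma = as.numeric(position_sigma),
    class_sigma = class_sigma
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  n <- length(cfg$sizes)
  # snap the angular bin to an exact integer divisor of the full turn so
  # that serialization round trips cannot move bin-edge pixels
  k <- 2 * pi / cfg$angular_bin
  if (abs(k - round(k)) < 1e-6 && round(k) >= 1) {
    cfg$angular_bin <- 2 * pi / round(k)
  }
  stopifnot(
    length(cfg$canvas) == 2, all(cfg$canvas >= 16),
    cfg$orientations >= 1,
    n >= 1, all(cfg$sizes >= 8),
    cfg$width_ratio > 1,
    all(cfg$sigma_l > 0), all(cfg$sigma_w > 0),
    length(cfg$sigma_l) == n, length(cfg$sigma_w) == n,
    cfg$gain_center > 0, all(cfg$gain_flank > 0),
    length(cfg$gain_flank) == n,
    length(cfg$degree_displacement) == n,
    all(cfg$degree_displacement > 0), all(cfg$degree_displacement <= 1.5),
    length(cfg$sign_displacement) == n,
    all(cfg$sign_displacement > 0), all(cfg$sign_displacement < 1),
    cfg$pool_subunits >= 1, cfg$pool_subunits %% 2 == 1,
    cfg$pool_spacing > 0,
    cfg$sigmoid_alpha > 0, cfg$sigmoid_beta_divisor > 0,
    cfg$straight_endstopped > 0, cfg$straight_endstopped < 1,
    cfg$straight_simple > 0, cfg$straight_simple < 1,
    cfg$radial_bin > 0, cfg$angular_bin > 0, cfg$max_radius > 0,
    length(cfg$position_sigma) == 2, all(cfg$position_sigma > 0),
    cfg$class_sigma > 0
  )
  if (length(cfg$aspect_ratios) != n) {
    stop("`aspect_ratios` must have one value per size (got ",
         length(cfg$aspect_ratios), " for ", n, " sizes)", call. = FALSE)
  }
  structure(cfg, class = "sc_config")
}

#' @export
print.sc_config <- function(x, ...) {
  cat("<sc_config>\n")
  cat("  canvas      :", paste(x$canvas, collapse = " x "), "px\n")
  cat("  bank        :", x$orientations, "orientations x",
      length(x$sizes), "sizes =", x$orientations * length(x$sizes),
      "filters\n")
  cat("  sizes       :", paste(x$sizes, collapse = ", "), "px\n")
  cat("  polar grid  :", n_radial_bins(x), "radial x", n_angular_bins(x),
      "angular bins\n")
  invisible(x)
}

# number of orientation channels / scales helpers
n_scales <- function(cfg) length(cfg$sizes)
orientation_angles <- function(cfg) {
  (seq_len(cfg$orientations) - 1) * pi / cfg$orientations
}
n_radial_bins <- function(cfg) as.integer(round(cfg$max_radius / cfg$radial_bin))
n_angular_bins <- function(cfg) as.integer(round(2 * pi / cfg$angular_bin))

#' Number of signed curvature classes
#'
#' Each degree-of-curvature scale splits into a convex-sign and a
#' concave-sign class, so the class count is twice the number of scales
#' (8 under the defaults).
#'
#' @param config An [model_config()] object.
#' @return Integer class count.
#' @export
n_curvature_classes <- function(config) 2L * n_scales(config)

#' Load a model configuration from YAML or JSON
#'
#' Absent fields take their default value from [model_config()]; unknown
#' keys are an error (they usually indicate a typo). An empty file yields
#' the full default configuration.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `sc_config` object.
#' @seealso [save_model_config()]
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(model_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_config, vals)
}

#' Save a model configuration
#'
#' Writes the configuration so that `load_model_config()` restores an
#' identical object.
#'
#' @param config An `sc_config` object.
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_model_config <- function(config, path) {
  stopifnot(inherits(config, "sc_config"))
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}

#' Run the full feedforward hierarchy on one image
#'
#' Computes every layer in order: simple -> complex -> endstopped (degree
#' and sign) -> signed local-curvature map.
#'
#' @param image A [stimulus_image()] (or plain matrix in `[0, 1]`).
#' @param config An [model_config()].
#' @param verbose Print per-stage timing and peak activation to `stderr`.
#' @return A list with elements `simple`, `complex`, `degree`, `sign_pos`,
#'   `sign_neg` (response stacks) and `curvature` (a curvature map).
#' @examples
#' cfg <- model_config(canvas = c(128, 128), sizes = 24, aspect_ratios = 1,
#'                     sigma_l = 8, sigma_w = 5, gain_flank = 1.2,
#'                     degree_displacement = 0.5, sign_displacement = 0.25)
#' img <- render_arc(radius = 20, canvas = c(128, 128))
#' out <- run_pipeline(img, cfg)
#' names(out)
#' @export
run_pipeline <- function(image, config = model_config(), verbose = FALSE) {
  image <- as_stimulus_image(image, canvas = config$canvas)
  stage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    if (verbose) {
      mx <- if (inherits(val, "curvature_map")) {
        max(val$classes)
      } else if (is.list(val)) {
        max(vapply(val[c("degree", "sign_pos", "sign_neg")], max, 0))
      } else {
        max(val)
      }
      message(sprintf("[%s] %.2fs, max activation %.4g", label,
                      proc.time()[["elapsed"]] - t0, mx))
    }
    val
  }
  simple <- stage("simple", simple_responses(image, config))
  complex <- stage("complex", complex_responses(simple))
  es <- stage("endstopped", endstopped_responses(simple, complex))
  curv <- stage("curvature",
                local_curvature_map(es$degree, es$sign_pos, es$sign_neg,
                                    simple, config,
                                    straight_stats = es$straight_stats))
  list(simple = simple, complex = complex, degree = es$degree,
       sign_pos = es$sign_pos, sign_neg = es$sign_neg, curvature = curv)
}
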