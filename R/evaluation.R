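#' Normalize a response vector to the unit range
#'
#' Divides by the designated template response when one is given (the
#' convention for shape-neuron profiles, whose template scores 1), and by
#' the maximum of the vector otherwise.
#'
#' @param raw Non-negative responses.
#' @param template_response Optional normalizer (> 0).
#' @return Responses on a `[0, 1]` scale (values may exceed 1 only when a
#'   stimulus outdrives the designated template).
#' @export
normalize_responses <- function(raw, template_response = NULL) {
  if (length(raw) == 0) stop("empty response vector", call. = FALSE)
  if (any(raw < 0)) stop("responses must be non-negative", call. = FALSE)
  denom <- if (is.null(template_response)) max(raw) else template_response
  if (denom <= 0) {
    stop("cannot normalize an all-zero response vector", call. = FALSE)
  }
  raw / denom
}

#' Mean absolute difference between response vectors
#'
#' The per-stimulus absolute difference between two normalized response
#' vectors, summarized by its mean and standard deviation. With responses
#' in `[0, 1]`, the mean lies in `[0, 1]` and is read as an error
#' fraction.
#'
#' @param model,reference Equal-length numeric vectors.
#' @return Named numeric `c(mean, stdev)`.
#' @examples
#' mean_abs_difference(c(1, 0), c(0, 1)) # mean 1, stdev 0
#' @export
mean_abs_difference <- function(model, reference) {
  if (length(model) != length(reference)) {
    stop("response vectors differ in length (", length(model), " vs ",
         length(reference), ")", call. = FALSE)
  }
  d <- abs(model - reference)
  c(mean = mean(d), stdev = if (length(d) > 1) stats::sd(d) else 0)
}

#' Build an isolation template by superposing strong stimuli
#'
#' Selects the stimuli whose (reference) responses reach the given
#' percentage of the maximum response and superimposes them by pixelwise
#' maximum. The result summarizes what drives a neuron and serves as the
#' template from which a model shape neuron is isolated. The default
#' reading of the cut ("70% maximum") keeps stimuli at or above 70% of
#' the maximum response; `method = "order_statistic"` instead keeps
#' stimuli at or above the 70th percentile of the response distribution.
#'
#' @param battery A battery tibble with an `image` list-column, or a list
#'   of stimulus images.
#' @param responses Numeric responses, one per stimulus.
#' @param percentile Cut level (percent).
#' @param method `"max_fraction"` (default) or `"order_statistic"`.
#' @return A [stimulus_image()] superposition.
#' @export
build_isolation_template <- function(battery, responses, percentile = 70,
                                     method = c("max_fraction",
                                                "order_statistic")) {
  method <- match.arg(method)
  battery <- as_battery(battery)
  if (nrow(battery) != length(responses)) {
    stop("battery and responses differ in length", call. = FALSE)
  }
  if (max(responses) <= 0) {
    stop("no stimulus has a positive response; cannot build a template",
         call. = FALSE)
  }
  cut <- if (method == "max_fraction") {
    (percentile / 100) * max(responses)
  } else {
    stats::quantile(responses, percentile / 100, names = FALSE)
  }
  sel <- which(responses >= cut)
  if (length(sel) == 0) stop("the percentile cut selects no stimuli",
                             call. = FALSE)
  imgs <- battery$image[sel]
  acc <- unclass(imgs[[1]])
  for (im in imgs[-1]) acc <- pmax(acc, unclass(im))
  stimulus_image(acc)
}

#' Compare model and reference response profiles
#'
#' Joins two long profile tables on (neuron, stimulus) and summarizes the
#' absolute difference between the normalized responses per neuron.
#'
#' @param model,reference Tibbles with columns `neuron`, `id` and
#'   `response` (responses already on a common `[0, 1]` normalization).
#' @return An `sc_comparison` tibble: per neuron the `mean_abs_diff`, its
#'   `stdev` and `n` (stimuli compared).
#' @export
comparison_report <- function(model, reference) {
  need <- c("neuron", "id", "response")
  stopifnot(all(need %in% names(model)), all(need %in% names(reference)))
  joined <- dplyr::inner_join(model, reference, by = c("neuron", "id"),
                              suffix = c("_model", "_ref"))
  if (nrow(joined) == 0) {
    stop("no (neuron, stimulus) pairs in common", call. = FALSE)
  }
  out <- joined |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(
      mean_abs_diff = mean(abs(.data$response_model - .data$response_ref)),
      stdev = stats::sd(abs(.data$response_model - .data$response_ref)),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(out, class = c("sc_comparison", class(tibble::tibble())))
}

#' @method glance sc_comparison
#' @export
glance.sc_comparison <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x),
    mean_error = mean(x$mean_abs_diff),
    sd_error = stats::sd(x$mean_abs_diff),
    battery_size = max(x$n)
  )
}

#' Isolate a shape neuron from a response profile
#'
#' The full isolation procedure: select the stimuli whose responses reach
#' `percentile`% of the maximum, and build a neuron from their curvature
#' parts. With `consensus = TRUE` (default) the neuron keeps only the
#' parts *consistently* present across the selected stimuli — each
#' (polar bin, class) part must occur in at least `coverage` of the
#' selected stimuli and reach `relevance` of the strongest retained part,
#' and its weight is the mean over the stimuli containing it. This is an
#' automatic analogue of pruning the superposed image down to the
#' relevant curvatures; `consensus = FALSE` instead superposes the
#' selected stimuli with [build_isolation_template()] and isolates from
#' the superposition directly.
#'
#' The neuron is normalized so that the strongest selected stimulus
#' evokes a response of 1.
#'
#' @param battery A battery tibble with list-columns `image` and/or
#'   `curvature` (see [add_curvature_maps()]).
#' @param responses Reference responses, one per battery row.
#' @param config An [model_config()].
#' @param percentile Selection cut (percent of the maximum response).
#' @param consensus Keep consistently shared parts (see above).
#' @param coverage Fraction of the selected stimuli a part must occur in.
#' @param relevance Minimum part weight as a fraction of the strongest.
#' @param origin Polar-grid origin mode, as in [isolate_shape_neuron()].
#' @return A `shape_neuron`.
#' @export
isolate_from_profile <- function(battery, responses,
                                 config = model_config(),
                                 percentile = 70, consensus = TRUE,
                                 coverage = 0.75, relevance = 0.3,
                                 origin = c("center", "centroid")) {
  origin <- match.arg(origin)
  battery <- as_battery(battery)
  if (nrow(battery) != length(responses)) {
    stop("battery and responses differ in length", call. = FALSE)
  }
  if (max(responses) <= 0) {
    stop("no stimulus has a positive response", call. = FALSE)
  }
  sel <- which(responses >= (percentile / 100) * max(responses))
  if (!consensus) {
    tmpl <- build_isolation_template(battery, responses, percentile)
    neuron <- isolate_shape_neuron(tmpl, config, origin = origin)
  } else {
    if (!"curvature" %in% names(battery)) {
      battery <- add_curvature_maps(battery, config)
    }
    tabs <- purrr::map(battery$curvature[sel], function(cm) {
      og <- resolve_origin(cm, origin, config)
      binned_curvature_records(cm, og, config) |>
        dplyr::group_by(.data$radial_bin, .data$angular_bin, .data$class,
                        .data$scale, .data$sign) |>
        dplyr::summarise(weight = max(.data$value), .groups = "drop")
    })
    weights <- dplyr::bind_rows(tabs) |>
      dplyr::group_by(.data$radial_bin, .data$angular_bin, .data$class,
                      .data$scale, .data$sign) |>
      dplyr::summarise(weight = sum(.data$weight) / length(sel),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n >= ceiling(coverage * length(sel))) |>
      dplyr::select(-"n")
    weights <- dplyr::filter(weights,
                             .data$weight >= relevance * max(.data$weight))
    if (nrow(weights) == 0) {
      stop("no curvature parts are shared by the selected stimuli",
           call. = FALSE)
    }
    neuron <- structure(
      list(weights = weights, origin_mode = origin, normalization = 1,
           config = config),
      class = "shape_neuron"
    )
    neuron$field <- smoothed_field(weights, config)
  }
  # normalize so the strongest selected stimulus scores 1
  stims <- if ("curvature" %in% names(battery)) battery$curvature else
    battery$image
  top <- max(vapply(stims[sel], function(s) shape_response(neuron, s),
                    numeric(1)))
  if (top <= 0) stop("isolated neuron does not respond to its own ",
                     "selection", call. = FALSE)
  neuron$normalization <- neuron$normalization * top
  neuron
}
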