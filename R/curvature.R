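#' Signed local-curvature map
#'
#' Convergence of the two endstopped populations: at each location and
#' scale, the degree-of-curvature response is routed into the convex-sign
#' class when the positive sign cell outresponds the negative one, into
#' the concave-sign class in the opposite case, and into neither on a tie.
#' With four degree scales this yields eight signed curvature classes.
#' Channels are pooled over orientations by the maximum, since the shape
#' layer reads out curvature, not orientation. Locations where every
#' endstopped cell is weak but a simple cell responds strongly are flagged
#' as straight (zero curvature) and carry no class response.
#'
#' @param degree,sign_pos,sign_neg Response stacks from
#'   [endstopped_responses()].
#' @param simple The simple-cell stack (for the straight rule).
#' @param config An [model_config()]; defaults to the stacks' config.
#' @return A `curvature_map`: list with `classes` (array height x width x
#'   class), `straight` (logical matrix) and `meta` (tibble of class,
#'   scale, sign).
#' @export
local_curvature_map <- function(degree, sign_pos, sign_neg, simple,
                                config = NULL, straight_stats = NULL) {
  if (is.null(config)) config <- attr(degree, "config")
  scales <- attr(degree, "scales")
  stopifnot(identical(dim(degree), dim(sign_pos)),
            identical(dim(degree), dim(sign_neg)),
            identical(dim(degree)[1:2], dim(simple)[1:2]))
  d <- dim(degree)
  n_sc <- length(scales)
  classes <- array(0, c(d[1], d[2], 2L * n_sc))
  for (si in seq_len(n_sc)) {
    # pool each population over orientations first, then route the degree
    # response by the pooled sign comparison: this keeps the two signed
    # planes of a scale mutually exclusive at every location
    dg <- matrix(0, d[1], d[2])
    sp <- matrix(0, d[1], d[2])
    sn <- matrix(0, d[1], d[2])
    for (oi in seq_len(d[3])) {
      dg <- pmax(dg, degree[, , oi, si])
      sp <- pmax(sp, sign_pos[, , oi, si])
      sn <- pmax(sn, sign_neg[, , oi, si])
    }
    classes[, , 2L * si - 1L] <- dg * (sp > sn)
    classes[, , 2L * si] <- dg * (sn > sp)
  }
  if (!config$keep_all_scales && n_sc > 1) {
    # winner-take-all over scales at each location
    strength <- vapply(seq_len(n_sc), function(si) {
      pmax(classes[, , 2L * si - 1L], classes[, , 2L * si])
    }, matrix(0, d[1], d[2]))
    win <- apply(strength, c(1, 2), which.max)
    for (si in seq_len(n_sc)) {
      keep <- win == si
      classes[, , 2L * si - 1L] <- classes[, , 2L * si - 1L] * keep
      classes[, , 2L * si] <- classes[, , 2L * si] * keep
    }
  }
  # straight rule: a location on a contour (strong simple response) whose
  # dominant orientation channel shows almost no endstopped response is a
  # straight segment and carries zero curvature
  s_pool <- matrix(0, d[1], d[2])
  for (si in seq_len(n_sc)) {
    for (oi in seq_len(d[3])) s_pool <- pmax(s_pool, simple[, , oi, si])
  }
  if (is.null(straight_stats)) {
    # fall back to recomputing the dominant-channel evidence from the
    # stacks given (exact when they carry pre-sigmoid responses)
    best_s <- matrix(-Inf, d[1], d[2])
    best_e <- matrix(0, d[1], d[2])
    for (si in seq_len(n_sc)) {
      for (oi in seq_len(d[3])) {
        s_map <- simple[, , oi, si]
        upd <- s_map > best_s
        best_s[upd] <- s_map[upd]
        e_map <- degree[, , oi, si]
        best_e[upd] <- e_map[upd]
      }
    }
    best_s[!is.finite(best_s)] <- 0
    straight_stats <- list(best_simple = best_s, best_degree_raw = best_e)
  }
  straight <- matrix(FALSE, d[1], d[2])
  if (max(s_pool) > 0) {
    straight <- (s_pool > config$straight_simple * max(s_pool)) &
      (straight_stats$best_degree_raw <
         config$straight_endstopped * straight_stats$best_simple)
    if (any(straight)) {
      for (k in seq_len(dim(classes)[3])) {
        classes[, , k] <- classes[, , k] * !straight
      }
    }
  }
  meta <- tibble::tibble(
    class = seq_len(2L * n_sc),
    scale = rep(scales, each = 2L),
    sign = rep(c("positive", "negative"), n_sc)
  )
  structure(list(classes = classes, straight = straight, meta = meta,
                 config = config),
            class = "curvature_map")
}

#' @export
print.curvature_map <- function(x, ...) {
  cat("<curvature_map> ", dim(x$classes)[1], "x", dim(x$classes)[2], " px, ",
      dim(x$classes)[3], " signed classes; ",
      sum(apply(x$classes, c(1, 2), max) > 0), " active px, ",
      sum(x$straight), " straight px\n", sep = "")
  invisible(x)
}

#' Compute the curvature map of a stimulus
#'
#' Convenience wrapper running simple, complex and endstopped layers and
#' combining them with [local_curvature_map()].
#'
#' @param image A [stimulus_image()].
#' @param config An [model_config()].
#' @param bank Optional [prepare_filter_bank()] cache.
#' @return A `curvature_map`.
#' @export
curvature_map <- function(image, config = model_config(), bank = NULL) {
  simple <- simple_responses(image, config, bank = bank)
  cx <- complex_responses(simple)
  es <- endstopped_responses(simple, cx)
  local_curvature_map(es$degree, es$sign_pos, es$sign_neg, simple, config,
                      straight_stats = es$straight_stats)
}

#' @method tidy curvature_map
#' @export
tidy.curvature_map <- function(x, ...) {
  recs <- purrr::map(seq_len(dim(x$classes)[3]), function(k) {
    plane <- x$classes[, , k]
    idx <- which(plane > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(x = idx[, 2] - 1, y = idx[, 1] - 1, class = k,
                   value = plane[idx])
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(x = numeric(), y = numeric(), class = integer(),
                          value = numeric())
  }
  dplyr::left_join(out, x$meta, by = "class")
}

#' Straight-flagged pixels of a curvature map
#'
#' @param x A `curvature_map`.
#' @return Tibble of 0-based `x`, `y` locations flagged as zero curvature.
#' @export
straight_pixels <- function(x) {
  idx <- which(x$straight, arr.ind = TRUE)
  tibble::tibble(x = idx[, 2] - 1, y = idx[, 1] - 1)
}
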