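#' Stimulus images
#'
#' All stimuli are grayscale images with a white contour (value 1) on a
#' black background (value 0), stored as a numeric matrix with rows
#' indexing y (downward) and columns indexing x (rightward).
#'
#' @section Coordinate convention:
#' Pixel coordinates are 0-based: the pixel in matrix cell `[row, col]`
#' has `x = col - 1`, `y = row - 1`. Angles are measured counter-clockwise
#' from the +x axis with y pointing down, so the unit vector of angle
#' `theta` is `(cos(theta), -sin(theta))` in `(x, y)`.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(pixels) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("stimulus_image", "matrix", "array"))
}

#' @rdname stimulus_image
#' @param x Object to coerce (matrix or `stimulus_image`).
#' @param canvas Optional expected dimensions, checked if given.
#' @export
as_stimulus_image <- function(x, canvas = NULL) {
  img <- if (inherits(x, "stimulus_image")) x else stimulus_image(as.matrix(x))
  if (!is.null(canvas) && !all(dim(img) == canvas)) {
    stop("image is ", nrow(img), "x", ncol(img), " px but the model canvas is ",
         canvas[1], "x", canvas[2], call. = FALSE)
  }
  img
}

#' @rdname stimulus_image
#' @export
blank_canvas <- function(canvas = c(400L, 400L)) {
  stimulus_image(matrix(0, canvas[1], canvas[2]))
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat("<stimulus_image> ", nrow(x), "x", ncol(x), " px, ",
      sum(x > 0), " foreground px\n", sep = "")
  invisible(x)
}

# canvas center in 0-based pixel coordinates
canvas_center <- function(canvas) c(floor(canvas[2] / 2), floor(canvas[1] / 2))

#' Foreground pixel records
#'
#' @param image A stimulus image.
#' @return A tibble with 0-based columns `x`, `y` and the pixel `value` of
#'   every foreground (> 0) pixel.
#' @export
pixel_coords <- function(image) {
  idx <- which(image > 0, arr.ind = TRUE)
  tibble::tibble(x = idx[, 2] - 1, y = idx[, 1] - 1,
                 value = image[idx])
}

# Rasterize a polyline given as continuous 0-based points.
# smooth = FALSE: round to nearest pixel, set to 1 (crisp binary contour).
# smooth = TRUE: distribute each sample bilinearly over its 4 neighbours,
# weighted by the arc length it represents, capped at 1 (anti-aliased).
rasterize_points <- function(xs, ys, canvas, smooth = FALSE, seglen = NULL) {
  img <- matrix(0, canvas[1], canvas[2])
  if (length(xs) == 0) return(stimulus_image(img))
  if (!smooth) {
    xi <- round(xs); yi <- round(ys)
    keep <- xi >= 0 & xi < canvas[2] & yi >= 0 & yi < canvas[1]
    img[cbind(yi[keep] + 1, xi[keep] + 1)] <- 1
  } else {
    if (is.null(seglen)) {
      seglen <- c(sqrt(diff(xs)^2 + diff(ys)^2), 0)
      seglen[length(seglen)] <- seglen[max(1, length(seglen) - 1)]
    }
    fx <- floor(xs); fy <- floor(ys)
    ax <- xs - fx; ay <- ys - fy
    X <- c(fx, fx + 1, fx, fx + 1)
    Y <- c(fy, fy, fy + 1, fy + 1)
    W <- c((1 - ax) * (1 - ay), ax * (1 - ay), (1 - ax) * ay, ax * ay) *
      rep(seglen, 4)
    keep <- X >= 0 & X < canvas[2] & Y >= 0 & Y < canvas[1] & W > 0
    if (any(keep)) {
      acc <- rowsum(W[keep], group = Y[keep] * canvas[2] + X[keep])
      lin <- as.numeric(rownames(acc))
      img[cbind(lin %/% canvas[2] + 1, lin %% canvas[2] + 1)] <-
        pmin(1, acc[, 1])
    }
  }
  stimulus_image(img)
}

#' Render a straight bar
#'
#' @param length Bar length in px (>= 1).
#' @param orientation Bar orientation in radians (counter-clockwise from
#'   +x; see [stimulus_image()] for the coordinate convention).
#' @param center Bar midpoint `(x, y)`, 0-based px; defaults to the canvas
#'   center.
#' @param thickness Contour thickness in px (>= 1).
#' @param canvas Canvas dimensions (height, width).
#' @param smooth Anti-alias the contour instead of crisp binary rounding.
#' @return A [stimulus_image()].
#' @examples
#' img <- render_bar(40, pi / 2)
#' sum(img > 0) > 0
#' @export
render_bar <- function(length, orientation, center = NULL, thickness = 1,
                       canvas = c(400L, 400L), smooth = FALSE) {
  stopifnot(length >= 1, thickness >= 1)
  if (is.null(center)) center <- canvas_center(canvas)
  u <- c(cos(orientation), -sin(orientation))
  ends_x <- center[1] + c(-1, 1) * (length / 2) * u[1]
  ends_y <- center[2] + c(-1, 1) * (length / 2) * u[2]
  if (any(ends_x < 0 | ends_x > canvas[2] - 1 | ends_y < 0 |
            ends_y > canvas[1] - 1)) {
    stop("bar of length ", length, " at (", center[1], ", ", center[2],
         ") extends outside the ", canvas[1], "x", canvas[2], " canvas",
         call. = FALSE)
  }
  n <- max(2L, ceiling(length / 0.25))
  t <- seq(-0.5, 0.5, length.out = n)
  perp <- c(-u[2], u[1])
  offs <- thickness_offsets(thickness)
  xs <- as.numeric(outer(center[1] + t * length * u[1], offs * perp[1], `+`))
  ys <- as.numeric(outer(center[2] + t * length * u[2], offs * perp[2], `+`))
  rasterize_points(xs, ys, canvas, smooth,
                   seglen = rep(length / (n - 1), n * length(offs)))
}

# sub-pixel offsets realizing a given contour thickness
thickness_offsets <- function(thickness) {
  if (thickness <= 1) return(0)
  seq(-(thickness - 1) / 2, (thickness - 1) / 2, by = 0.5)
}

#' Render a circular arc
#'
#' The arc is the set of points at distance `radius` from `center`, at
#' angles within `angular_extent` around `orientation` (the angle of the
#' arc midpoint as seen from the circle center). `angular_extent = 2 * pi`
#' draws a full circle.
#'
#' @param radius Circle radius in px (> 0).
#' @param center Circle center `(x, y)`, 0-based px; defaults to canvas
#'   center.
#' @param angular_extent Arc extent in radians, in `(0, 2 * pi]`.
#' @param orientation Angle of the arc midpoint, radians.
#' @inheritParams render_bar
#' @return A [stimulus_image()].
#' @examples
#' circle <- render_arc(radius = 150)
#' contour_centroid(circle)
#' @export
render_arc <- function(radius, center = NULL, angular_extent = 2 * pi,
                       orientation = 0, thickness = 1,
                       canvas = c(400L, 400L), smooth = FALSE) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  stopifnot(angular_extent > 0, angular_extent <= 2 * pi + 1e-12,
            thickness >= 1)
  if (is.null(center)) center <- canvas_center(canvas)
  offs <- thickness_offsets(thickness)
  full <- angular_extent >= 2 * pi - 1e-12
  xs <- numeric(0); ys <- numeric(0); sl <- numeric(0)
  for (o in offs) {
    r <- radius + o
    # absolute angular grid so that complementary arcs partition a circle
    # into identical pixel sets
    delta <- pi / max(16L, ceiling(8 * r))
    a0 <- orientation - angular_extent / 2
    a1 <- orientation + angular_extent / 2
    k <- seq(ceiling(a0 / delta - 1e-9), ceiling(a1 / delta - 1e-9) - 1)
    if (full) k <- seq(ceiling(a0 / delta - 1e-9),
                       length.out = round(2 * pi / delta))
    ang <- k * delta
    xs <- c(xs, center[1] + r * cos(ang))
    ys <- c(ys, center[2] - r * sin(ang))
    sl <- c(sl, rep(r * delta, length(ang)))
  }
  rasterize_points(xs, ys, canvas, smooth, seglen = sl)
}

#' Boundary elements of closed shapes
#'
#' A boundary element is a local feature of a closed contour: a sharp
#' convex corner, or a convex/concave curve of medium or high curvature,
#' placed at an angular position around the shape.
#'
#' @param kind One of `"sharp_convex_angle"`, `"medium_convex"`,
#'   `"high_convex"`, `"medium_concave"`, `"high_concave"`.
#' @param angular_position Angular position of the element on the contour,
#'   radians.
#' @param radial_extent Radial amplitude of the element in px; `NA` (the
#'   default) uses a kind-specific fraction of the shape's base radius.
#' @return A one-row tibble usable in [render_closed_shape()].
#' @export
boundary_element <- function(kind, angular_position, radial_extent = NA) {
  kinds <- c("sharp_convex_angle", "medium_convex", "high_convex",
             "medium_concave", "high_concave")
  kind <- match.arg(kind, kinds)
  tibble::tibble(kind = kind, angular_position = angular_position,
                 radial_extent = as.numeric(radial_extent))
}

# per-kind radial bump profile parameters (relative amplitude, angular width)
element_profile <- function(kind) {
  switch(kind,
    sharp_convex_angle = list(amp = 0.55, width = 0.55, shape = "triangle"),
    medium_convex      = list(amp = 0.28, width = 0.40, shape = "gauss"),
    high_convex        = list(amp = 0.45, width = 0.24, shape = "gauss"),
    medium_concave     = list(amp = -0.28, width = 0.40, shape = "gauss"),
    high_concave       = list(amp = -0.45, width = 0.26, shape = "gauss"),
    stop("unknown boundary element kind: ", kind, call. = FALSE)
  )
}

# smallest signed angular difference, in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Render a closed shape from boundary elements
#'
#' The contour is a star-shaped closed curve: a radial profile
#' `r(phi) = r0 + sum of element bumps` traced over the full circle.
#' Convex elements bulge outward, concave elements indent inward; the
#' sharp convex angle uses a triangular (slope-discontinuous) profile so
#' that it renders as a true corner. The whole shape spans approximately
#' `span` px and is rotated rigidly about the canvas center.
#'
#' @param elements Boundary elements: a tibble from rows of
#'   [boundary_element()] (or a list of them).
#' @param rotation Rigid rotation of the whole shape, radians
#'   (counter-clockwise). The stimulus batteries use multiples of `pi / 4`.
#' @param span Approximate shape diameter in px.
#' @inheritParams render_bar
#' @return A [stimulus_image()].
#' @examples
#' four <- dplyr::bind_rows(
#'   boundary_element("medium_convex", 0),
#'   boundary_element("medium_convex", pi / 2),
#'   boundary_element("medium_convex", pi),
#'   boundary_element("medium_convex", 3 * pi / 2))
#' img <- render_closed_shape(four)
#' @export
render_closed_shape <- function(elements, rotation = 0, span = 300,
                                thickness = 1, canvas = c(400L, 400L),
                                smooth = FALSE) {
  if (inherits(elements, "data.frame")) {
    el <- elements
  } else {
    el <- dplyr::bind_rows(elements)
  }
  if (nrow(el) == 0) stop("at least one boundary element is required",
                          call. = FALSE)
  r0 <- 0.32 * span
  phi <- seq(0, 2 * pi, length.out = 4096L + 1L)[-(4096L + 1L)]
  r <- rep(r0, length(phi))
  for (i in seq_len(nrow(el))) {
    prof <- element_profile(el$kind[i])
    amp <- if (is.na(el$radial_extent[i])) prof$amp * r0 else
      sign(prof$amp) * el$radial_extent[i]
    d <- angle_diff(phi, el$angular_position[i])
    bump <- if (prof$shape == "triangle") {
      pmax(0, 1 - abs(d) / prof$width)
    } else {
      exp(-d^2 / (2 * prof$width^2))
    }
    r <- r + amp * bump
  }
  if (any(r <= 2)) {
    stop("boundary elements do not form a closed contour: ",
         "the radial profile collapses through the shape center",
         call. = FALSE)
  }
  ctr <- canvas_center(canvas)
  psi <- phi + rotation
  xs <- ctr[1] + r * cos(psi)
  ys <- ctr[2] - r * sin(psi)
  rasterize_points(xs, ys, canvas, smooth)
}

#' Centroid of a contour image
#'
#' Mean position of the foreground pixels, weighted by pixel intensity
#' (all weights equal for crisp binary stimuli).
#'
#' @param image A stimulus image with at least one foreground pixel.
#' @return Numeric `(x, y)`, 0-based px.
#' @export
contour_centroid <- function(image) {
  px <- pixel_coords(image)
  if (nrow(px) == 0) stop("cannot compute the centroid of an empty image",
                          call. = FALSE)
  w <- px$value / sum(px$value)
  c(x = sum(px$x * w), y = sum(px$y * w))
}

#' Built-in base shapes for the stimulus battery
#'
#' Twelve closed-shape specifications mixing sharp convex corners with
#' medium and high convex and concave boundary elements at multiples of
#' 45 degrees.
#'
#' @return A named list of boundary-element tibbles.
#' @export
default_shape_specs <- function() {
  e <- boundary_element
  list(
    circle4 = dplyr::bind_rows(e("medium_convex", 0), e("medium_convex", pi / 2),
                               e("medium_convex", pi), e("medium_convex", 3 * pi / 2)),
    teardrop = dplyr::bind_rows(e("sharp_convex_angle", pi / 2),
                                e("medium_convex", 3 * pi / 2)),
    kite = dplyr::bind_rows(e("sharp_convex_angle", 0), e("medium_convex", pi / 2),
                            e("medium_convex", pi), e("medium_convex", 3 * pi / 2)),
    dent1 = dplyr::bind_rows(e("medium_concave", 0), e("high_convex", pi / 2),
                             e("high_convex", 3 * pi / 2)),
    dent2 = dplyr::bind_rows(e("high_concave", 0), e("sharp_convex_angle", 3 * pi / 4),
                             e("sharp_convex_angle", 5 * pi / 4)),
    blob2 = dplyr::bind_rows(e("high_convex", pi / 4), e("high_convex", 5 * pi / 4)),
    tri = dplyr::bind_rows(e("sharp_convex_angle", pi / 2),
                           e("sharp_convex_angle", 7 * pi / 6),
                           e("sharp_convex_angle", 11 * pi / 6)),
    pear = dplyr::bind_rows(e("high_convex", pi / 2), e("medium_concave", pi),
                            e("medium_convex", 3 * pi / 2), e("medium_concave", 0)),
    wedge = dplyr::bind_rows(e("sharp_convex_angle", 0), e("high_concave", pi)),
    lobed = dplyr::bind_rows(e("high_convex", 0), e("medium_concave", pi / 2),
                             e("high_convex", pi), e("medium_concave", 3 * pi / 2)),
    snail = dplyr::bind_rows(e("sharp_convex_angle", pi / 4),
                             e("medium_concave", pi),
                             e("high_convex", 3 * pi / 2)),
    bean = dplyr::bind_rows(e("medium_convex", 0), e("high_concave", 3 * pi / 4),
                            e("medium_convex", 3 * pi / 2))
  )
}

#' Generate a rotated, deduplicated stimulus battery
#'
#' Renders each base shape at `rotations` evenly spaced rotations (45
#' degree steps by default) and drops duplicate images, which arise when a
#' base shape has rotational symmetry.
#'
#' @param specs Named list of boundary-element tibbles; defaults to the
#'   built-in base set.
#' @param rotations Number of evenly spaced rotations over the full turn.
#' @param dedupe Drop rotations that render to an identical image.
#' @inheritParams render_closed_shape
#' @return A tibble with columns `id`, `base`, `rotation` and a list-column
#'   `image` of [stimulus_image()] objects.
#' @examples
#' battery <- stimulus_battery(rotations = 2)
#' nrow(battery)
#' @export
stimulus_battery <- function(specs = default_shape_specs(), rotations = 8L,
                             dedupe = TRUE, span = 300,
                             canvas = c(400L, 400L), smooth = FALSE) {
  stopifnot(rotations >= 1)
  if (is.null(names(specs))) names(specs) <- paste0("shape", seq_along(specs))
  rows <- purrr::imap(specs, function(spec, nm) {
    purrr::map(seq_len(rotations) - 1L, function(k) {
      rot <- k * 2 * pi / rotations
      img <- render_closed_shape(spec, rotation = rot, span = span,
                                 canvas = canvas, smooth = smooth)
      tibble::tibble(base = nm, rotation = rot, image = list(img))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (dedupe) {
    h <- purrr::map_chr(out$image, rlang::hash)
    out <- out[!duplicated(h), ]
  }
  out$id <- sprintf("%s_r%03d", out$base, round(out$rotation * 180 / pi))
  dplyr::relocate(out, "id")
}

#' Read and write stimulus images
#'
#' PNG files go through the png package; PGM files (P2 ASCII and P5
#' binary) are handled directly. Written pixels are scaled to 8-bit gray.
#'
#' @param image A [stimulus_image()].
#' @param path File path ending in `.png` or `.pgm`.
#' @return `write_stimulus()` returns `path` invisibly; `read_stimulus()`
#'   returns a [stimulus_image()].
#' @export
write_stimulus <- function(image, path) {
  image <- as_stimulus_image(image)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(unclass(image), path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(image), nrow(image)), "255"), con)
    writeBin(as.integer(round(t(unclass(image)) * 255)), con, size = 1)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    return(stimulus_image(m))
  }
  if (!grepl("\\.pgm$", path, ignore.case = TRUE)) {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  toks <- character(0)
  while (length(toks) < 3) {
    ln <- readLines(con, n = 1)
    ln <- sub("#.*", "", ln)
    toks <- c(toks, strsplit(trimws(ln), "\\s+")[[1]])
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2])
  maxval <- as.integer(toks[3])
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else if (magic == "P2") {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    stop("not a PGM file: ", path, call. = FALSE)
  }
  stimulus_image(matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE))
}
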