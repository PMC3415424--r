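test_that("bars render at the requested length, orientation and position", {
  img <- render_bar(40, pi / 2, canvas = c(160L, 160L))
  px <- pixel_coords(img)
  expect_gt(nrow(px), 0)
  # vertical: a single column of pixels spanning 40 +- 1 px
  expect_equal(length(unique(px$x)), 1)
  expect_lte(abs(diff(range(px$y)) - 40), 1)

  # degenerate one-pixel bar
  dot <- render_bar(1, 0, canvas = c(160L, 160L))
  expect_lte(sum(dot > 0), 2)

  # principal axis recovered by the image-moments oracle within 2 degrees
  for (th in c(pi / 6, 5 * pi / 12, 2 * pi / 3)) {
    b <- render_bar(80, th, canvas = c(160L, 160L))
    err <- abs(moments_orientation(b) - th) %% pi
    expect_lt(min(err, pi - err), 2 * pi / 180)
  }

  expect_error(render_bar(500, 0, canvas = c(160L, 160L)), "canvas")
})

test_that("arcs follow the requested circle and compose exactly", {
  circle <- render_arc(radius = 60, canvas = c(160L, 160L))
  ctr <- contour_centroid(circle)
  expect_lt(max(abs(ctr - c(80, 80))), 1)

  # least-squares circle fit recovers the radius within the thickness
  for (r in c(25, 60)) {
    img <- render_arc(radius = r, canvas = c(160L, 160L))
    fit <- circle_fit(img)
    expect_lt(abs(fit$radius - r), 1)
  }

  # a full circle equals the union of two complementary half-turn arcs
  full <- render_arc(50, canvas = c(160L, 160L))
  h1 <- render_arc(50, angular_extent = pi, orientation = pi / 2,
                   canvas = c(160L, 160L))
  h2 <- render_arc(50, angular_extent = pi, orientation = 3 * pi / 2,
                   canvas = c(160L, 160L))
  expect_identical(unclass(full), unclass(pmax(unclass(h1), unclass(h2))))

  expect_error(render_arc(-3), "radius")
  expect_error(render_arc(0), "radius")
})

test_that("rendering is deterministic", {
  a <- render_closed_shape(default_shape_specs()$kite, rotation = pi / 4)
  b <- render_closed_shape(default_shape_specs()$kite, rotation = pi / 4)
  expect_identical(unclass(a), unclass(b))
})

test_that("closed shapes honour their boundary elements", {
  # four medium convexities at the cardinals give a near-circular contour
  four <- default_shape_specs()$circle4
  img <- render_closed_shape(four, canvas = c(400L, 400L))
  px <- pixel_coords(img)
  r <- sqrt((px$x - 200)^2 + (px$y - 200)^2)
  expect_lt(stats::sd(r) / mean(r), 0.06)

  # a full-turn rotation is pixel-identical
  base <- render_closed_shape(default_shape_specs()$kite)
  turned <- render_closed_shape(default_shape_specs()$kite,
                                rotation = 2 * pi)
  expect_identical(unclass(base), unclass(turned))

  # the single sharp corner is the unique locus of maximal turning angle
  # (discrete-curvature oracle on the contour traced by polar angle)
  spec <- dplyr::bind_rows(
    boundary_element("sharp_convex_angle", pi / 2),
    boundary_element("medium_convex", 7 * pi / 6),
    boundary_element("medium_convex", 11 * pi / 6)
  )
  img <- render_closed_shape(spec, canvas = c(400L, 400L))
  px <- pixel_coords(img)
  ang <- atan2(-(px$y - 200), px$x - 200) %% (2 * pi)
  ord <- order(ang)
  xs <- px$x[ord]; ys <- px$y[ord]
  idx <- seq(1, length(xs), by = 6)   # subsample to tame pixel jitter
  xs <- xs[idx]; ys <- ys[idx]
  n <- length(xs)
  turn <- vapply(seq_len(n), function(i) {
    p0 <- c(xs[(i - 2) %% n + 1], ys[(i - 2) %% n + 1])
    p1 <- c(xs[i], ys[i])
    p2 <- c(xs[i %% n + 1], ys[i %% n + 1])
    v1 <- p1 - p0; v2 <- p2 - p1
    abs(atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)))
  }, numeric(1))
  peak_angle <- ang[ord][idx][which.max(turn)]
  d <- abs(peak_angle - pi / 2) %% (2 * pi)
  expect_lt(min(d, 2 * pi - d), 0.3)

  # an element sequence that collapses the radial profile does not close
  bad <- dplyr::bind_rows(
    boundary_element("high_concave", 0, radial_extent = 500),
    boundary_element("medium_convex", pi)
  )
  expect_error(render_closed_shape(bad), "close")
})

test_that("contour centroid is the intensity-weighted pixel mean", {
  img <- blank_canvas(c(160L, 160L))
  m <- unclass(img)
  m[20 + 1, 10 + 1] <- 1          # pixel (x = 10, y = 20)
  expect_equal(contour_centroid(stimulus_image(m)), c(x = 10, y = 20))

  set.seed(42)
  m2 <- matrix(0, 160, 160)
  idx <- cbind(sample(160, 50, TRUE), sample(160, 50, TRUE))
  m2[idx] <- 1
  got <- contour_centroid(stimulus_image(m2))
  px <- which(m2 > 0, arr.ind = TRUE)
  expect_equal(unname(got), c(mean(px[, 2] - 1), mean(px[, 1] - 1)))

  expect_error(contour_centroid(blank_canvas(c(20L, 20L))), "empty")
})

test_that("rotating a shape rotates its centroid about the canvas center", {
  spec <- default_shape_specs()$teardrop
  for (k in 1:3) {
    th <- k * pi / 4
    c0 <- contour_centroid(render_closed_shape(spec))
    c1 <- contour_centroid(render_closed_shape(spec, rotation = th))
    v <- c0 - c(200, 200)
    expected <- c(200, 200) + c(v[1] * cos(th) + v[2] * sin(th),
                                -v[1] * sin(th) + v[2] * cos(th))
    expect_lt(max(abs(c1 - expected)), 1)
  }
})

test_that("stimulus batteries rotate, deduplicate and label their members", {
  bat <- stimulus_battery(specs = default_shape_specs()[c("circle4", "kite")],
                          rotations = 4L, canvas = c(200L, 200L), span = 150)
  expect_true(all(c("id", "base", "rotation", "image") %in% names(bat)))
  # the four-fold symmetric shape collapses under deduplication
  expect_lt(sum(bat$base == "circle4"), 4)
  expect_equal(sum(bat$base == "kite"), 4)
  expect_false(any(duplicated(bat$id)))
})

test_that("stimulus images round-trip through PNG and PGM", {
  img <- render_closed_shape(default_shape_specs()$tri,
                             canvas = c(160L, 160L), span = 100)
  for (ext in c("png", "pgm")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_stimulus(img, path)
    back <- read_stimulus(path)
    expect_equal(unclass(back), unclass(img), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})
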