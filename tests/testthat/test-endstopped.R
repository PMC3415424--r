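cfg <- small_config()

layers_for <- function(img, config = cfg) {
  s <- simple_responses(img, config)
  cx <- complex_responses(s)
  list(simple = s, complex = cx,
       es = endstopped_responses(s, cx))
}

test_that("endstopped responses vanish without contours", {
  l <- layers_for(blank_canvas(c(160L, 160L)))
  expect_equal(max(l$es$degree), 0)
  expect_equal(max(l$es$sign_pos), 0)
  expect_equal(max(l$es$sign_neg), 0)
})

test_that("degree cells are length tuned: short bars beat long bars", {
  # a bar that fits the center simple cell excites without reaching the
  # flankers; bars extending past the cell drive the inhibitory flankers
  oi <- 5  # vertical channel
  lens <- c(8, 12, 16, 20, 28, 40, 60, 120)
  resp <- vapply(lens, function(len) {
    l <- layers_for(render_bar(len, pi / 2, canvas = c(160L, 160L)))
    max(stack_channel(l$es$degree, 1, oi))
  }, numeric(1))
  best <- lens[which.max(resp)]
  expect_lte(best, 1.2 * cfg$sizes[1])     # optimum near or below cell size
  expect_gt(max(resp), resp[lens == 120])  # long bars are endstopped
  expect_gt(max(resp), 0)
})

test_that("sign variants prefer opposite bend directions and swap under mirroring", {
  oi <- 5
  right <- layers_for(side_arc(20, side = 1))
  left <- layers_for(side_arc(20, side = -1))
  pr <- stack_channel(right$es$sign_pos, 1, oi)[81, 81]
  nr <- stack_channel(right$es$sign_neg, 1, oi)[81, 81]
  pl <- stack_channel(left$es$sign_pos, 1, oi)[81, 81]
  nl <- stack_channel(left$es$sign_neg, 1, oi)[81, 81]
  # one variant prefers the rightward bulge, the other the mirrored arc
  expect_gt(max(pr, nr), 0)
  expect_true((pr > nr) != (pl > nl))
  # mirroring the stimulus swaps the two variants' responses
  expect_equal(pr, nl, tolerance = 1e-6)
  expect_equal(nr, pl, tolerance = 1e-6)
})

test_that("a straight bar drives both sign variants equally", {
  oi <- 5
  l <- layers_for(render_bar(140, pi / 2, canvas = c(160L, 160L)))
  p <- stack_channel(l$es$sign_pos, 1, oi)[81, 81]
  n <- stack_channel(l$es$sign_neg, 1, oi)[81, 81]
  expect_gt(max(p, n), 0)
  expect_lt(abs(p - n) / max(p, n), 0.05)
})

test_that("reflection about a cell's preferred axis swaps the sign maps", {
  # Reflecting the stimulus about a cell's preferred axis turns a bend
  # one way into a bend the other way, so the two sign variants swap;
  # reflecting about the perpendicular axis leaves the bend direction
  # unchanged and each variant maps to itself (at the mirrored channel).
  n_o <- cfg$orientations
  w <- 160L
  relerr <- function(a, b) max(abs(a - b)) / max(b, 1e-12)

  # x-flip: the vertical channel sees its preferred axis as the mirror
  img <- side_arc(24, side = 1)
  a <- layers_for(img)
  b <- layers_for(stimulus_image(unclass(img)[, w:1]))
  expect_lt(relerr(stack_channel(b$es$sign_pos, 1, 5)[, w:1],
                   stack_channel(a$es$sign_neg, 1, 5)), 1e-8)
  # oblique channels swap across the mirrored channel pair (45 <-> 135)
  expect_lt(relerr(stack_channel(b$es$sign_pos, 1, (n_o - 2) %% n_o + 1)[, w:1],
                   stack_channel(a$es$sign_neg, 1, 3)), 1e-8)
  # the horizontal channel is reflected about its perpendicular axis:
  # bend direction is preserved, so each variant maps to itself
  expect_lt(relerr(stack_channel(b$es$sign_pos, 1, 1)[, w:1],
                   stack_channel(a$es$sign_pos, 1, 1)), 1e-8)

  # y-flip: now the horizontal channel swaps variants
  up <- render_arc(24, center = c(80, 104), angular_extent = pi,
                   orientation = pi / 2, canvas = c(160L, 160L),
                   smooth = TRUE)
  u <- layers_for(up)
  v <- layers_for(stimulus_image(unclass(up)[w:1, ]))
  expect_lt(relerr(stack_channel(v$es$sign_pos, 1, 1)[w:1, ],
                   stack_channel(u$es$sign_neg, 1, 1)), 1e-8)
})

test_that("the output sigmoid is monotone and anchored at zero", {
  expect_equal(response_sigmoid(0, 0.01, 5), 0)
  x <- seq(0, 100, 0.5)
  g <- response_sigmoid(x, 0.05, 20)
  expect_true(all(diff(g) >= 0))
  expect_lt(max(g), 1)
  # zero half-saturation (a silent scale) maps everything to zero
  expect_equal(response_sigmoid(x, 0.05, 0), x * 0)
})

test_that("raising contrast never lowers endstopped responses", {
  img <- side_arc(20, side = 1)
  lo <- layers_for(stimulus_image(unclass(img) * 0.5))
  hi <- layers_for(img)
  expect_true(all(unclass(hi$es$degree) - unclass(lo$es$degree) >= -1e-9))
})

test_that("curvature tuning curves normalize and expose their band", {
  # a single sampled radius (taken where the cell responds) self-normalizes
  sweep2 <- curvature_tuning_curve(2, seq(16, 40, 4), cfg)
  rpk <- sweep2$radius[which.max(sweep2$response)]
  one <- curvature_tuning_curve(2, rpk, cfg)
  expect_equal(one$response_norm, 1)
  b <- attr(one, "band")
  expect_equal(unname(b), c(rpk, rpk))

  curve <- curvature_tuning_curve(1, seq(3, 8, 1), cfg)
  expect_equal(max(curve$response_norm), 1)
  expect_true(all(curve$response >= 0))
  expect_error(curvature_tuning_curve(1, numeric(0), cfg), "non-empty")
  expect_error(curvature_tuning_curve(1, c(5, -2), cfg), "> 0")
})

test_that("probe tuning agrees with the full response maps at the apex", {
  # dual route: the probe computes the same quantity as the map pipeline
  # read out at the apex pixel on the tangent-matched channel
  radii <- c(20, 24, 32)
  probe <- curvature_tuning_curve(2, radii, cfg, pool = "probe")
  for (i in seq_along(radii)) {
    img <- shapecurv:::tuning_arc(radii[i], cfg$canvas)
    l <- layers_for(img)
    es_raw <- endstopped_responses(l$simple, l$complex,
                                   apply_sigmoid = FALSE)
    apex <- stack_channel(es_raw$degree, 2, 5)[81, 81]
    # the two routes rectify and interpolate in opposite orders, which
    # leaves a small discrepancy where subunit responses straddle zero
    expect_equal(apex, probe$response[i], tolerance = 0.02)
  }
  # and the image-pooled maximum dominates the single-cell probe
  mapped <- curvature_tuning_curve(2, radii, cfg, pool = "image")
  expect_gte(min(mapped$response - 0.98 * probe$response), 0)
})

test_that("band_90pct matches a brute-force threshold scan", {
  # triangular synthetic curve with a known band
  radii <- 1:21
  resp <- pmax(0, 10 - abs(radii - 11))
  band <- band_90pct(tibble::tibble(radius = radii, response = resp))
  # brute force: fine grid scan for the 0.9-of-max crossings
  fine <- seq(1, 21, 0.001)
  vals <- stats::approx(radii, resp, fine)$y
  keep <- fine[vals >= 0.9 * max(resp)]
  expect_equal(unname(band), c(min(keep), max(keep)), tolerance = 1e-3)

  # single point at the maximum
  one <- band_90pct(tibble::tibble(radius = c(5, 9), response = c(1, 0)))
  expect_equal(unname(one), c(5, 5 + 0.4))
  expect_error(band_90pct(tibble::tibble(radius = 1:3, response = rep(0, 3))),
               "zero")
})
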