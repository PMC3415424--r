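cfg <- small_config()

test_that("DoG kernels are even-symmetric, zero-mean line detectors", {
  k1 <- dog_kernel(21, sigma_l = 8, sigma_w = 4, orientation = pi / 3)
  k2 <- dog_kernel(21, sigma_l = 8, sigma_w = 4, orientation = pi / 3 + pi)
  expect_equal(k1, k2)
  expect_lt(abs(sum(k1)), 1e-10)
  expect_equal(sum(k1^2), 1)
  expect_error(dog_kernel(2, 1, 1), "support")

  # responds more to a bar at the preferred orientation than orthogonal
  # (brute-force dot product against explicitly rendered bars)
  for (th in c(0, pi / 4, 2 * pi / 3)) {
    k <- dog_kernel(41, sigma_l = 15, sigma_w = 5, orientation = th)
    pref <- render_bar(35, th, center = c(20, 20), canvas = c(41L, 41L))
    orth <- render_bar(35, th + pi / 2, center = c(20, 20),
                       canvas = c(41L, 41L))
    expect_gt(sum(k * unclass(pref)), sum(k * unclass(orth)))
  }
})

test_that("the filter bank has one member per orientation-size pair", {
  expect_equal(nrow(filter_bank(model_config())), 48)
  one <- model_config(orientations = 4L, sizes = 20, aspect_ratios = 1,
                      sigma_l = 8, sigma_w = 5, gain_flank = 1,
                      degree_displacement = 0.5, sign_displacement = 0.25)
  expect_equal(nrow(filter_bank(one)), 4)
  two <- model_config(orientations = 12L, sizes = c(20, 40),
                      aspect_ratios = c(1, 2), sigma_l = c(8, 16),
                      sigma_w = c(5, 5), gain_flank = c(1, 1),
                      degree_displacement = c(0.5, 0.5),
                      sign_displacement = c(0.25, 0.25))
  expect_equal(nrow(filter_bank(two)), 24)
  expect_error(model_config(sizes = c(20, 40), aspect_ratios = c(1, 2, 3),
                            sigma_l = c(8, 16), sigma_w = c(5, 5),
                            gain_flank = c(1, 1),
                            degree_displacement = c(0.5, 0.5),
                            sign_displacement = c(0.25, 0.25)),
               "aspect_ratios")
})

test_that("simple responses rectify, localize and scale linearly", {
  # uniform image: zero-DC kernels give a zero stack away from the
  # zero-padded border (where a uniform gray field presents an edge)
  flat <- stimulus_image(matrix(0.5, 160, 160))
  s_flat <- simple_responses(flat, cfg)
  interior <- 21:140
  expect_lt(max(s_flat[interior, interior, , ]), 1e-8)
  expect_equal(max(simple_responses(blank_canvas(c(160L, 160L)), cfg)), 0)

  # stack dimensions mirror the bank layout
  expect_equal(dim(s_flat), c(160L, 160L, 8L, 2L))

  # a vertical bar peaks in the 90-degree channel at the bar center
  bar <- render_bar(60, pi / 2, canvas = c(160L, 160L))
  s <- simple_responses(bar, cfg)
  center_resp <- s[81, 81, , 1]
  expect_equal(which.max(center_resp),
               which.min(abs(shapecurv:::orientation_angles(cfg) - pi / 2)))

  # responses are linear in contrast before the output sigmoid
  half <- stimulus_image(unclass(bar) * 0.5)
  s_half <- simple_responses(half, cfg)
  expect_equal(unclass(s_half), unclass(s) * 0.5, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("simple responses match an independent convolution oracle", {
  skip_if_not_installed("EBImage")
  img <- side_arc(25, canvas = c(160L, 160L), smooth = FALSE)
  s <- simple_responses(img, cfg)
  fb <- filter_bank(cfg)
  row <- fb[fb$scale == 1 & fb$orientation_index == 3, ]
  k <- bank_kernel(row)
  ref <- EBImage::filter2(unclass(img), k, boundary = 0)
  ref[ref < 0] <- 0
  expect_equal(s[, , 3, 1], ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("complex pooling preserves level, rectifies and adds tolerance", {
  # a constant simple stack passes through unchanged at interior pixels
  # because the five subunit weights are normalized to sum to one
  const <- simple_responses(blank_canvas(c(160L, 160L)), cfg)
  v <- array(0.7, dim(const))
  const_stack <- shapecurv:::new_response_stack(v, cfg, 1:2, "simple")
  cx <- complex_responses(const_stack)
  expect_equal(cx[81, 81, 1, 1], 0.7, tolerance = 1e-10)

  # zero in, zero out
  z <- complex_responses(const)
  expect_equal(max(z), 0)

  # complex responses tolerate a 3 px lateral shift better than simple
  bar <- render_bar(60, pi / 2, canvas = c(160L, 160L))
  shifted <- render_bar(60, pi / 2, center = c(83, 80),
                        canvas = c(160L, 160L))
  oi <- 5  # 90-degree channel under 8 orientations
  s0 <- simple_responses(bar, cfg)
  s1 <- simple_responses(shifted, cfg)
  c0 <- complex_responses(s0)
  c1 <- complex_responses(s1)
  rel_s <- abs(s1[81, 81, oi, 1] - s0[81, 81, oi, 1]) / s0[81, 81, oi, 1]
  rel_c <- abs(c1[81, 81, oi, 1] - c0[81, 81, oi, 1]) / c0[81, 81, oi, 1]
  expect_lt(rel_c, rel_s)

  # and are spatially smoother across the contour
  prof_s <- s0[81, , oi, 1]
  prof_c <- c0[81, , oi, 1]
  expect_lt(mean(abs(diff(prof_c))), mean(abs(diff(prof_s))))
})

test_that("rotating the stimulus by 90 degrees permutes orientation channels", {
  bar0 <- render_bar(60, 0, canvas = c(160L, 160L))
  bar90 <- render_bar(60, pi / 2, canvas = c(160L, 160L))
  s0 <- simple_responses(bar0, cfg)
  s90 <- simple_responses(bar90, cfg)
  a0 <- which.max(s0[81, 81, , 1])
  a90 <- which.max(s90[81, 81, , 1])
  expect_equal((a0 - 1 + cfg$orientations / 2) %% cfg$orientations,
               (a90 - 1) %% cfg$orientations)
})

test_that("compiled bilinear shift agrees with the reference implementation", {
  set.seed(7)
  m <- matrix(rnorm(400), 20, 20)
  for (d in list(c(0, 0), c(3, -2), c(1.4, 2.7), c(-5.25, 0.5),
                 c(25, 0), c(-0.01, 19.99))) {
    expect_equal(shapecurv:::shift_image(m, d[1], d[2]),
                 shapecurv:::shift_image_ref(m, d[1], d[2]),
                 tolerance = 1e-12)
  }
})
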