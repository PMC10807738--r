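make_wedge_image <- function(greys = c(1000, 2000, 3000, 4000, 5000),
                             step_w = 12, h = 60, noise_sd = 0, seed = 1) {
  k <- length(greys)
  img <- matrix(500, h, k * step_w + 20)
  for (i in seq_len(k)) {
    img[11:(h - 10), (10 + (i - 1) * step_w + 1):(10 + i * step_w)] <- greys[i]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
  }
  img
}

test_that("wedge steps are detected and sampled to the true band means", {
  greys <- c(1000, 2000, 3000, 4000, 5000)
  img <- make_wedge_image(greys)
  spec <- wedge_spec(1:5, roi = c(10, 10, 60, 40), margin = 2)
  regions <- detect_wedge(img, spec)
  expect_length(regions, 5)
  means <- vapply(regions, `[[`, numeric(1), "mean_grey")
  expect_equal(means, greys, tolerance = 1)

  # with Gaussian noise the eroded bands still sample the right pixels
  imgn <- make_wedge_image(greys, noise_sd = 20, seed = 99)
  regn <- detect_wedge(imgn, spec)
  for (i in 1:5) {
    # >99% of eroded-band pixels belong to the true band (here: all of them,
    # checked against the noiseless ground-truth masks)
    truth <- img[regn[[i]]$rows, regn[[i]]$cols]
    expect_gt(mean(truth == greys[i]), 0.99)
  }
  expect_error(detect_wedge(img, wedge_spec(1:5, c(200, 10, 60, 40))),
               "outside image")
  # too few distinct bands
  flat <- matrix(1000, 60, 80)
  expect_error(detect_wedge(flat, spec), "wedge detection failed")
})

test_that("calibration interpolates, hits knots exactly, and clamps", {
  img <- make_wedge_image(c(100, 200), step_w = 20)
  spec <- wedge_spec(c(1, 2), roi = c(10, 10, 40, 40), margin = 2)
  curve <- build_calibration(detect_wedge(img, spec), img, spec)
  expect_equal(as.numeric(predict(curve, 150)), 1.5)
  expect_equal(as.numeric(predict(curve, 100)), 1.0)
  v <- predict(curve, 250)
  expect_equal(as.numeric(v), 2.0)
  expect_true(attr(v, "clamped"))
  expect_false(attr(predict(curve, 150), "clamped"))
  # monotone evaluation
  g <- seq(50, 300, by = 10)
  expect_true(all(diff(as.numeric(predict(curve, g))) >= 0))
  # non-monotone knots (inverted photometric interpretation) error out
  inv <- 300 - img
  expect_error(build_calibration(detect_wedge(inv, spec), inv, spec),
               "non-monotone")
})

test_that("subchondral circles follow the 1/20 fractions and tangency", {
  ls <- rect_landmarks()   # AB = CD = 150, L3: y = 100, L2: y = 90
  fw <- build_framework(ls)
  circ <- place_subchondral_circles(fw, "lateral", "tibia")
  expect_equal(circ$r, rep(150 / 40, 4))               # diameter 7.5 px
  expect_equal(circ$cy, rep(100 + 150 / 40, 4))        # tangent below L3
  expect_equal(diff(sort(circ$cx)), rep(7.5, 3))       # mutual spacing S/20
  # lateral circles march inward from the outer perpendicular at station 20
  expect_equal(sort(abs(circ$cx - fw$A[1])), c(20, 27.5, 35, 42.5))
  # tangency: nearest distance to the joint line is zero
  expect_equal(abs(line_signed_dist(fw$L3, cbind(circ$cx, circ$cy))) - circ$r,
               rep(0, 4), tolerance = 1e-9)
  # femoral circles strictly above L2, tibial strictly below L3
  fem <- place_subchondral_circles(fw, "medial", "femur")
  expect_true(all(fem$cy < 90))
  expect_true(all(circ$cy > 100))
  # non-overlap within a group
  d <- as.matrix(dist(cbind(fem$cx, fem$cy)))
  expect_true(all(d[upper.tri(d)] >= 2 * fem$r[1] - 1e-9))
  # circles outside the image raise a placement error
  expect_error(place_subchondral_circles(fw, "lateral", "tibia",
                                         image_dim = c(60, 60)),
               "outside image")
})

test_that("intensity measurement converts circle means through the curve", {
  p <- phantom_params()
  ph <- generate_phantom(p)
  can <- canonicalize(ph$landmarks, p$width)
  fw <- build_framework(can)
  calib <- build_calibration(detect_wedge(ph$image, ph$wedge),
                             ph$image, ph$wedge)
  res <- measure_intensities(ph$image, fw, calib)
  expect_equal(nrow(res$circles), 16L)
  expect_equal(nrow(res$summary), 4L)
  tib <- res$summary$mean_mmal[res$summary$bone == "tibia"]
  fem <- res$summary$mean_mmal[res$summary$bone == "femur"]
  expect_equal(tib, rep(ph$truth$mmal[["tibia_medial"]], 2), tolerance = 1e-9)
  expect_equal(fem, rep(ph$truth$mmal[["femur_medial"]], 2), tolerance = 1e-9)
})

test_that("mmAl outputs are invariant to affine photometric transforms", {
  p <- phantom_params()
  ph <- generate_phantom(p)
  can <- canonicalize(ph$landmarks, p$width)
  fw <- build_framework(can)
  measure_with <- function(img) {
    calib <- build_calibration(detect_wedge(img, ph$wedge), img, ph$wedge)
    measure_intensities(img, fw, calib)$summary$mean_mmal
  }
  base <- measure_with(ph$image)
  shifted <- measure_with(ph$image + 1234)
  scaled <- measure_with(1.7 * ph$image + 250)
  expect_equal(shifted, base, tolerance = 1e-6)
  expect_equal(scaled, base, tolerance = 1e-6)
})
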