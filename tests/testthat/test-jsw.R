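test_that("parallel plates give constant diameter equal to the gap", {
  ls <- rect_landmarks(plateau_y = 100, condyle_y = 90)
  fw <- build_framework(ls)
  res <- measure_jsw(ls, fw, pixel_spacing = 0.2)
  expect_equal(res$n_circles, 30L)
  expect_equal(nrow(res$circles), 30L)
  expect_equal(res$mean_medial_jsw_mm, 2.0, tolerance = 1e-6)
  expect_equal(res$mean_lateral_jsw_mm, 2.0, tolerance = 1e-6)
  expect_equal(res$minimal_jsw_mm, 2.0, tolerance = 1e-6)
  expect_true(all(abs(res$circles$diameter_px - 10) < 1e-4))
  # units: doubling pixel spacing doubles mm outputs, px diameters unchanged
  res2 <- measure_jsw(ls, fw, pixel_spacing = 0.4)
  expect_equal(res2$mean_medial_jsw_mm, 2 * res$mean_medial_jsw_mm)
  expect_equal(res2$circles$diameter_px, res$circles$diameter_px)
})

test_that("clipped boundaries stay on the original polylines and flag extrapolation", {
  ls <- rect_landmarks()
  fw <- build_framework(ls)
  b <- clip_boundaries(ls, fw, "lateral")
  # clipped vertices lie on the original horizontal boundaries
  expect_true(all(abs(b$upper[, 2] - 90) < 1e-9))
  expect_true(all(abs(b$lower[, 2] - 100) < 1e-9))
  # spans exactly the band in stations along L3
  su <- kneemorph:::poly_su(b, b$lower)
  expect_equal(range(su$s), c(20, 42.5), tolerance = 1e-9)
  expect_false(b$extrapolated_lower)

  # a band reaching beyond the annotated range flags extrapolation
  p <- phantom_params(x_medial = 60, x_lateral = 320)
  ph <- generate_phantom(p)
  can <- canonicalize(ph$landmarks, p$width)
  fw_w <- build_framework(can)
  bw <- clip_boundaries(can, fw_w, "lateral")
  expect_true(bw$extrapolated_lower || bw$extrapolated_upper)
})

test_that("inscribed circles match a dense grid-search oracle on wedge gaps", {
  # deterministic wedge-gap fixture: tilted upper plate
  for (theta in c(1, 3, 6)) {
    p <- phantom_params(femoral_tilt_deg = theta)
    ph <- generate_phantom(p)
    can <- canonicalize(ph$landmarks, p$width)
    fw <- build_framework(can)
    b <- clip_boundaries(can, fw, "lateral")
    for (station in c(25, 33, 41)) {
      circ <- inscribed_circle_at(b, station)
      expect_equal(circ$radius, brute_force_radius(b, station),
                   tolerance = 1e-3)
      # contact contract: touches both boundaries, crosses neither
      du <- kneemorph:::point_poly_dist(circ$center, b$upper)
      dl <- kneemorph:::point_poly_dist(circ$center, b$lower)
      expect_gte(du, circ$radius - 1e-4)
      expect_gte(dl, circ$radius - 1e-4)
      expect_lte(min(du, dl), circ$radius + 1e-3)
    }
  }
})

test_that("touching or crossing boundaries give zero radius, never negative", {
  b <- random_gap_boundary()
  b$upper[, 2] <- b$lower[, 2]   # gap closed everywhere
  circ <- inscribed_circle_at(b, 30)
  expect_equal(circ$radius, 0)
  b$upper[, 2] <- b$lower[, 2] + 5  # upper strictly below lower: crossing
  circ2 <- inscribed_circle_at(b, 30)
  expect_equal(circ2$radius, 0)
  expect_true(circ2$crossing)
})

test_that("minimal JSW lands at the narrow corner of a uniformly tilted gap", {
  p <- phantom_params(femoral_tilt_deg = 2)  # narrows toward lateral (+x)
  ph <- generate_phantom(p)
  can <- canonicalize(ph$landmarks, p$width)
  fw <- build_framework(can)
  res <- measure_jsw(can, fw, p$pixel_spacing)
  lat <- res$circles[res$circles$compartment == "lateral", ]
  # gap shrinks toward the lateral corner = smaller station along A->B
  expect_equal(which.min(lat$diameter_mm), which.min(lat$station_px))
  expect_equal(res$minimal_jsw_compartment, "lateral")
})

test_that("JSW is rigid-invariant and monotone in the gap", {
  ls <- rect_landmarks()
  fw <- build_framework(ls)
  base <- measure_jsw(ls, fw, 0.2)
  lsr <- rotate_landmarks(ls, 11, center = c(75, 95))
  fwr <- build_framework(lsr)
  rot <- measure_jsw(lsr, fwr, 0.2)
  expect_equal(sort(rot$circles$diameter_px), sort(base$circles$diameter_px),
               tolerance = 1e-4)
  # enlarge the gap: translate every femoral landmark up by 3 px
  ls2 <- ls
  ls2$points[58:99, 2] <- ls2$points[58:99, 2] - 3
  fw2 <- build_framework(ls2)
  wider <- measure_jsw(ls2, fw2, 0.2)
  expect_true(all(wider$circles$diameter_px >=
                    base$circles$diameter_px - 1e-6))
})

test_that("per-circle CSV export has one row per circle plus a summary", {
  ls <- rect_landmarks()
  fw <- build_framework(ls)
  res <- measure_jsw(ls, fw, 0.2)
  tf <- tempfile(fileext = ".csv")
  write_jsw_csv(res, tf)
  df <- read.csv(tf)
  expect_equal(nrow(df), 31L)
  expect_equal(sum(df$compartment == "summary"), 1L)
})
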