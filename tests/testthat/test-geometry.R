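test_that("supporting lines touch the set and keep all points on one side", {
  # collinear extremes: apex on the far side, line through the two extremes
  l <- supporting_line(rbind(c(0, 0), c(1, -1), c(2, 0)), c(0, 1))
  expect_equal(abs(line_signed_dist(l, c(0, 0))), 0, tolerance = 1e-9)
  expect_equal(abs(line_signed_dist(l, c(2, 0))), 0, tolerance = 1e-9)
  expect_equal(l$dir[2], 0)

  # two points force the line through both
  l2 <- supporting_line(rbind(c(0, 0), c(3, 4)), c(1, 0))
  expect_lt(abs(line_signed_dist(l2, c(0, 0))), 1e-9)
  expect_lt(abs(line_signed_dist(l2, c(3, 4))), 1e-9)

  # coincident points are degenerate
  expect_error(supporting_line(rbind(c(1, 1), c(1, 1)), c(0, 1)),
               "degenerate")

  # property: random convex clouds, random contact directions
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:25, 1)
    pts <- cbind(runif(n, -10, 10), runif(n, -10, 10))
    th <- runif(1, 0, 2 * pi)
    contact <- c(cos(th), sin(th))
    l <- supporting_line(pts, contact)
    sd <- line_signed_dist(l, pts)
    # contact side is positive along the normal: nothing beyond the line
    expect_lte(max(sd), 1e-6)
    # the line touches at least one point
    expect_lte(min(abs(sd)), 1e-6)
    # normal agrees with the contact direction
    expect_gt(sum(l$normal * contact), 0)
  }
})

test_that("supporting line of circle points is the brute-force best hull edge", {
  set.seed(7)
  th <- sort(runif(40, 0, 2 * pi))
  pts <- cbind(5 * cos(th), 5 * sin(th))
  l <- supporting_line(pts, c(0, 1))
  # brute force: try every pair of points, keep feasible supporting pairs,
  # pick the one whose outward normal best aligns with +y
  best <- -Inf
  for (i in 1:39) for (j in (i + 1):40) {
    d <- (pts[j, ] - pts[i, ]); d <- d / sqrt(sum(d^2))
    for (sgn in c(-1, 1)) {
      nrm <- sgn * c(-d[2], d[1])
      side <- (pts[, 1] - pts[i, 1]) * nrm[1] + (pts[, 2] - pts[i, 2]) * nrm[2]
      if (max(side) <= 1e-9) best <- max(best, nrm[2])
    }
  }
  expect_equal(sum(l$normal * c(0, 1)), best, tolerance = 1e-9)
  expect_lte(max(line_signed_dist(l, pts)), 1e-6)
})

test_that("framework matches the closed-form rectangular fixture", {
  ls <- rect_landmarks()
  fw <- build_framework(ls)
  expect_equal(fw$AB, 150)
  expect_equal(fw$CD, 150)
  # L3 at y = 100, L2 at y = 90
  expect_equal(fw$A[2], 100); expect_equal(fw$B[2], 100)
  expect_equal(fw$C[2], 90); expect_equal(fw$D[2], 90)
  # A lateral (x = 150 in this frame), B medial (x = 0)
  expect_equal(fw$A[1], 150); expect_equal(fw$B[1], 0)
  # stations: outer 2/15 * 150 = 20 from each corner, inner +3/20 * 150
  expect_equal(fw$bands$lateral$tibia$outer, 20)
  expect_equal(fw$bands$lateral$tibia$inner, 42.5)
  expect_equal(fw$bands$medial$tibia$outer, 130)
  expect_equal(fw$bands$medial$tibia$inner, 107.5)
  expect_equal(fw$bands$lateral$femur$outer, 20)
  expect_equal(fw$bands$medial$femur$inner, 107.5)
})

test_that("framework is rigid-invariant and scales with similarity", {
  ls <- rect_landmarks()
  fw0 <- build_framework(ls)
  fw_rot <- build_framework(rotate_landmarks(ls, 7))
  expect_equal(fw_rot$AB, fw0$AB, tolerance = 1e-6)
  expect_equal(fw_rot$CD, fw0$CD, tolerance = 1e-6)
  expect_equal(fw_rot$bands$lateral$tibia$inner,
               fw0$bands$lateral$tibia$inner, tolerance = 1e-6)
  fw_scaled <- build_framework(scale_landmarks(ls, 2))
  expect_equal(fw_scaled$AB, 2 * fw0$AB, tolerance = 1e-9)
  expect_equal(fw_scaled$CD, 2 * fw0$CD, tolerance = 1e-9)
  expect_equal(fw_scaled$bands$medial$tibia$outer / fw_scaled$AB,
               fw0$bands$medial$tibia$outer / fw0$AB, tolerance = 1e-12)
  # bands never cross for the whole phantom suite
  for (p in phantom_suite()) {
    ph <- generate_phantom(p)
    can <- canonicalize(ph$landmarks, p$width)
    fw <- build_framework(can)
    expect_lt(fw$bands$lateral$tibia$inner, fw$bands$medial$tibia$inner)
  }
})

test_that("perpendiculars are orthogonal and hit the station point", {
  ls <- rect_landmarks()
  fw <- build_framework(ls)
  # station 20 from A = (150, 100) toward B gives the vertical line x = 130
  perp <- perpendicular_at(fw$tibial_axis, 20)
  expect_equal(perp$point, c(130, 100))
  expect_equal(sum(perp$dir * fw$tibial_axis$dir), 0)
  # station at the corner passes through the corner
  perp0 <- perpendicular_at(fw$tibial_axis, 0)
  expect_equal(perp0$point, fw$A)
})

test_that("framework serializes to JSON", {
  fw <- build_framework(rect_landmarks())
  js <- jsonlite::fromJSON(framework_json(fw))
  expect_equal(js$AB, 150)
  expect_equal(js$corners$A, c(150, 100))
})
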