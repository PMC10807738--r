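# Shared fixtures: all built in code at test time.

# a rectangular "textbook" landmark layout: horizontal plateau at y = 100,
# condyles at y = 90, vertical shaft edges at x = 0 and x = 150
rect_landmarks <- function(plateau_y = 100, condyle_y = 90,
                           x_med = 0, x_lat = 150) {
  p <- phantom_params(width = 200L, height = 200L,
                      x_medial = x_med, x_lateral = x_lat,
                      tibial_y = plateau_y,
                      gap_center_px = plateau_y - condyle_y,
                      eminence_medial_px = 25, eminence_lateral_px = 30,
                      wedge_roi = c(155, 5, 36, 20),
                      wedge_thicknesses_mm = c(2, 4),
                      wedge_greys = c(6000, 12000))
  ls <- landmark_set(kneemorph:::phantom_landmarks_right(p),
                     laterality = "right")
  canonicalize(ls, 200)
}

# apply a rigid rotation (about a center) to a landmark set
rotate_landmarks <- function(ls, angle_deg, center = c(100, 100)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- ls
  out$points <- sweep(sweep(ls$points, 2, center) %*% t(R), 2, center, `+`)
  out
}

scale_landmarks <- function(ls, factor) {
  out <- ls
  out$points <- ls$points * factor
  out
}

# brute-force station-constrained inscribed-circle radius by dense 1D grid
# over center positions along the perpendicular (independent of the
# golden-section implementation)
brute_force_radius <- function(boundary, station, coarse = 1e-2, fine = 1e-5) {
  ax <- boundary$axis
  u <- boundary$updir
  p0 <- ax$point + station * ax$dir
  rad <- function(t) {
    cen <- p0 + t * u
    min(kneemorph:::point_poly_dist(cen, boundary$upper),
        kneemorph:::point_poly_dist(cen, boundary$lower))
  }
  su_up <- kneemorph:::poly_su(boundary, boundary$upper)
  su_lo <- kneemorph:::poly_su(boundary, boundary$lower)
  u_up <- stats::approx(su_up$s, su_up$u, xout = station, rule = 2, ties = "ordered")$y
  u_lo <- stats::approx(su_lo$s, su_lo$u, xout = station, rule = 2, ties = "ordered")$y
  if (u_up <= u_lo) return(0)
  tg <- seq(u_lo, u_up, by = coarse)
  rg <- vapply(tg, rad, numeric(1))
  t0 <- tg[which.max(rg)]
  tg2 <- seq(t0 - 2 * coarse, t0 + 2 * coarse, by = fine)
  max(vapply(tg2, rad, numeric(1)))
}

# a random convex-gap joint boundary fixture: concave-down upper polyline,
# concave-up lower polyline, clipped to a band
random_gap_boundary <- function() {
  xs <- seq(0, 60, by = 6)
  upper_y <- 80 - runif(1, 2, 10) - runif(1, 0.01, 0.08) * (xs - 30)^2 / 30
  lower_y <- 100 + runif(1, 0.01, 0.08) * (xs - 30)^2 / 30
  axis <- new_line(c(0, 100), c(1, 0), canonicalize = FALSE)
  structure(
    list(compartment = "lateral",
         upper = cbind(xs, upper_y), lower = cbind(xs, lower_y),
         band = list(outer = 10, inner = 50),
         axis = axis, updir = c(0, -1),
         extrapolated_upper = FALSE, extrapolated_lower = FALSE),
    class = "joint_boundary"
  )
}

default_cfg <- function(ph) {
  run_config(pixel_spacing = ph$params$pixel_spacing,
             laterality = ph$params$laterality, wedge = ph$wedge)
}

# the reproducibility batch: n phantoms with varied geometry and bone greys
reproducibility_batch <- function(n = 20, base_seed = 1) {
  lapply(seq_len(n), function(i) {
    phantom_params(
      tibial_tilt_deg = c(0, 1, -1, 0.5)[1 + (i %% 4)],
      femoral_tilt_deg = c(1.5, 0, -0.8, 2)[1 + (i %% 4)],
      gap_center_px = 18 + (i %% 5) * 3,
      eminence_medial_px = 45 + (i %% 4) * 5,
      eminence_lateral_px = 55 + (i %% 3) * 5,
      tibia_grey = 15000 + 400 * i,
      femur_grey = 19000 + 300 * i,
      noise_sd = 25, seed = base_seed * 1000L + i
    )
  })
}
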