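# Synthetic knee-radiograph phantoms with closed-form ground truth.
#
# A phantom renders two bone-plate bands (femur above, tibia below) whose
# facing edges realize specified straight joint lines, stamps an aluminum
# step wedge with known mm thicknesses and grey levels, and places the 99
# landmarks analytically on the rendered edges so the geometric ground
# truth is exact. Image rendering exists to exercise the intensity path;
# geometry never depends on it.

#' Parameters of a synthetic knee phantom
#'
#' Default values describe a plausible posteroanterior knee radiograph at
#' 0.2 mm/px: a 40 mm wide joint, a 5 mm joint space, eminence apexes 11 and
#' 13 mm proximal to the tibial joint line, and a six-step aluminum wedge
#' spanning 2-12 mm.
#'
#' The tibial joint line is `y = tibial_y + tan(tibial_tilt) * (x - xc)` and
#' the femoral joint line `y = (tibial_y - gap_center_px) +
#' tan(femoral_tilt) * (x - xc)` with `xc` the joint midline; their tilt
#' difference is the ground-truth JLCA, and the vertical distance between
#' them the joint-space gap profile (constant when the tilts are equal,
#' linear otherwise).
#'
#' @param width,height image size in px.
#' @param pixel_spacing mm per pixel.
#' @param x_medial,x_lateral shaft edge x positions (canonical frame:
#'   lateral on the +x side).
#' @param tibial_y tibial joint line y at the joint midline (px).
#' @param tibial_tilt_deg,femoral_tilt_deg joint line tilts in degrees.
#' @param gap_center_px joint-space gap at the joint midline (px, >= 0
#'   across the joint).
#' @param eminence_medial_px,eminence_lateral_px eminence apex heights above
#'   the tibial joint line (perpendicular px).
#' @param tibia_grey,femur_grey,background_grey rendered grey levels.
#' @param wedge_thicknesses_mm,wedge_greys step thicknesses (mm Al,
#'   ascending) and their rendered grey levels (ascending with thickness).
#' @param wedge_roi wedge region `c(x, y, w, h)` (0-based px).
#' @param wedge_margin erosion margin for wedge sampling (px).
#' @param noise_sd Gaussian grey noise standard deviation (0 = noiseless).
#' @param seed RNG seed, mandatory whenever `noise_sd > 0`.
#' @param laterality `"right"` or `"left"`; left phantoms are rendered
#'   mirrored, with mirrored landmarks and wedge ROI.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(width = 384L, height = 384L, pixel_spacing = 0.2,
                           x_medial = 90, x_lateral = 290,
                           tibial_y = 220, tibial_tilt_deg = 0,
                           femoral_tilt_deg = 0, gap_center_px = 25,
                           eminence_medial_px = 55, eminence_lateral_px = 65,
                           tibia_grey = 18000, femur_grey = 21000,
                           background_grey = 3000,
                           wedge_thicknesses_mm = seq(2, 12, by = 2),
                           wedge_greys = seq(6000, 26000, by = 4000),
                           wedge_roi = c(8, 8, 84, 40), wedge_margin = 2L,
                           noise_sd = 0, seed = 1L,
                           laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(length(wedge_thicknesses_mm) == length(wedge_greys),
            all(diff(wedge_thicknesses_mm) > 0), all(diff(wedge_greys) > 0),
            pixel_spacing > 0, x_lateral > x_medial)
  p <- list(width = as.integer(width), height = as.integer(height),
            pixel_spacing = pixel_spacing,
            x_medial = x_medial, x_lateral = x_lateral,
            tibial_y = tibial_y, tibial_tilt_deg = tibial_tilt_deg,
            femoral_tilt_deg = femoral_tilt_deg, gap_center_px = gap_center_px,
            eminence_medial_px = eminence_medial_px,
            eminence_lateral_px = eminence_lateral_px,
            tibia_grey = tibia_grey, femur_grey = femur_grey,
            background_grey = background_grey,
            wedge_thicknesses_mm = wedge_thicknesses_mm,
            wedge_greys = wedge_greys, wedge_roi = wedge_roi,
            wedge_margin = as.integer(wedge_margin),
            noise_sd = noise_sd, seed = as.integer(seed),
            laterality = laterality)
  xc <- (x_medial + x_lateral) / 2
  gap <- phantom_gap(p, c(x_medial, x_lateral))
  if (any(gap < 0)) {
    stop("generation error: joint lines cross inside the joint", call. = FALSE)
  }
  class(p) <- "phantom_params"
  p
}

# joint line y values and the vertical gap profile
phantom_yt <- function(p, x) {
  xc <- (p$x_medial + p$x_lateral) / 2
  p$tibial_y + tan(deg2rad(p$tibial_tilt_deg)) * (x - xc)
}
phantom_yf <- function(p, x) {
  xc <- (p$x_medial + p$x_lateral) / 2
  (p$tibial_y - p$gap_center_px) + tan(deg2rad(p$femoral_tilt_deg)) * (x - xc)
}
phantom_gap <- function(p, x) phantom_yt(p, x) - phantom_yf(p, x)

# analytic landmark placement in the canonical (right-knee) frame
phantom_landmarks_right <- function(p) {
  xm <- p$x_medial; xl <- p$x_lateral
  xc <- (xm + xl) / 2
  yt <- function(x) phantom_yt(p, x)
  yf <- function(x) phantom_yf(p, x)
  pts <- matrix(NA_real_, 99, 2)
  set_pt <- function(i, x, y) pts[i, ] <<- c(x, y)

  ytm <- yt(xm); ytl <- yt(xl)
  yfm <- yf(xm); yfl <- yf(xl)

  # tibia: medial shaft (2-7 region, point 7 at the medial plateau corner)
  set_pt(1, xm, ytm + 130)
  shaft_y <- c(100, 80, 60, 40, 20, 0)
  for (k in 1:6) set_pt(1 + k, xm, ytm + shaft_y[k])
  set_pt(8, xm + 8, yt(xm + 8) + 4)
  # medial anterior plateau (9-13) exactly on the tibial joint line
  med_x <- xm + c(6, 20, 34, 48, 62)
  for (k in 1:5) set_pt(8 + k, med_x[k], yt(med_x[k]))
  set_pt(14, xc - 10, yt(xc - 10) + 6)
  # eminence apexes (15 medial-side, 19 lateral-side), perpendicular offsets
  n3 <- eminence_normal(p)
  fm <- c(xc - 18, yt(xc - 18))
  fl <- c(xc + 18, yt(xc + 18))
  set_pt(15, fm[1] + p$eminence_medial_px * n3[1],
         fm[2] + p$eminence_medial_px * n3[2])
  set_pt(16, xc - 6, yt(xc - 6) + 4)
  set_pt(17, xc, yt(xc) + 6)
  set_pt(18, xc + 6, yt(xc + 6) + 4)
  set_pt(19, fl[1] + p$eminence_lateral_px * n3[1],
         fl[2] + p$eminence_lateral_px * n3[2])
  # lateral anterior plateau (20-25) on the joint line; 26 at the corner
  lat_x <- xl - c(62, 48, 34, 20, 10, 4)
  for (k in 1:6) set_pt(19 + k, lat_x[k], yt(lat_x[k]))
  set_pt(26, xl, ytl)
  # lateral tibial shaft (26-32 on the shaft edge)
  lat_shaft <- c(15, 35, 55, 75, 95, 115)
  for (k in 1:6) set_pt(26 + k, xl, ytl + lat_shaft[k])
  set_pt(33, xc - 20, yt(xc - 20) + 60)
  set_pt(34, xc + 20, yt(xc + 20) + 60)
  # posterior medial plateau markers just distal to the joint line
  set_pt(35, xm + 25, yt(xm + 25) + 5)
  set_pt(36, xm + 45, yt(xm + 45) + 5)
  # tibial filler rows (37-57)
  fill_x <- seq(xm + 10, xl - 10, length.out = 11)
  for (k in 1:11) set_pt(36 + k, fill_x[k], yt(fill_x[k]) + 80)
  fill_x2 <- seq(xm + 15, xl - 15, length.out = 10)
  for (k in 1:10) set_pt(47 + k, fill_x2[k], yt(fill_x2[k]) + 95)

  # femur: medial shaft (58-62), condyle transition 63-64, condyle 65-68
  fem_shaft <- c(100, 80, 60, 40, 20)
  for (k in 1:5) set_pt(57 + k, xm, yfm - fem_shaft[k])
  con_x <- xm + c(6, 16, 30, 44, 56, 66)
  for (k in 1:6) set_pt(62 + k, con_x[k], yf(con_x[k]))
  set_pt(69, xc, yf(xc) - 40)
  # lateral condyle (70-75) on the femoral joint line
  conl_x <- xl - c(66, 56, 44, 30, 16, 6)
  for (k in 1:6) set_pt(69 + k, conl_x[k], yf(conl_x[k]))
  # lateral femoral shaft (76-80)
  for (k in 1:5) set_pt(75 + k, xl, yfl - c(20, 40, 60, 80, 100)[k])
  # patella cluster (81-89), interior so it touches no framework line
  th <- seq(0, 2 * pi, length.out = 10)[1:9]
  for (k in 1:9) {
    set_pt(80 + k, xc + 25 * cos(th[k]), yf(xc) - 100 + 20 * sin(th[k]))
  }
  # lateral femoral curve continuation (90-98) further proximal on the shaft
  for (k in 1:9) set_pt(89 + k, xl, yfl - (100 + 10 * k))
  set_pt(99, xc, yf(xc) - 60)
  pts
}

# unit normal of the tibial joint line pointing toward the femur (-y side)
eminence_normal <- function(p) {
  d <- unit_vec(c(1, tan(deg2rad(p$tibial_tilt_deg))))
  n <- rot90ccw(d)
  if (n[2] > 0) n <- -n
  n
}

# closed-form expected measurements, independent of the measurement code
phantom_truth <- function(p, n_per_compartment = 15L) {
  th_t <- deg2rad(p$tibial_tilt_deg)
  th_f <- deg2rad(p$femoral_tilt_deg)
  phi <- abs(th_f - th_t)
  AB <- (p$x_lateral - p$x_medial) / cos(th_t)
  x_of_station <- function(s) p$x_lateral - s * cos(th_t)
  diam_at <- function(s) {
    d0 <- phantom_gap(p, x_of_station(s)) * cos(th_f)
    2 * d0 / (1 + cos(phi))
  }
  band <- function(from_far) {
    outer <- if (from_far) AB - (2 / 15) * AB else (2 / 15) * AB
    inner <- if (from_far) outer - (3 / 20) * AB else outer + (3 / 20) * AB
    i <- seq_len(n_per_compartment)
    outer + (i - 0.5) / n_per_compartment * (inner - outer)
  }
  d_lat <- vapply(band(FALSE), diam_at, numeric(1))
  d_med <- vapply(band(TRUE), diam_at, numeric(1))
  mmal_of <- function(grey) {
    stats::approx(p$wedge_greys, p$wedge_thicknesses_mm, xout = grey,
                  rule = 2)$y
  }
  list(
    mean_medial_jsw_mm = mean(d_med) * p$pixel_spacing,
    mean_lateral_jsw_mm = mean(d_lat) * p$pixel_spacing,
    minimal_jsw_mm = min(c(d_med, d_lat)) * p$pixel_spacing,
    jlca_deg = abs(p$femoral_tilt_deg - p$tibial_tilt_deg),
    eminence_medial_mm = p$eminence_medial_px * p$pixel_spacing,
    eminence_lateral_mm = p$eminence_lateral_px * p$pixel_spacing,
    mmal = c(tibia_medial = mmal_of(p$tibia_grey),
             tibia_lateral = mmal_of(p$tibia_grey),
             femur_medial = mmal_of(p$femur_grey),
             femur_lateral = mmal_of(p$femur_grey)),
    pixel_spacing = p$pixel_spacing
  )
}

# render the 16-bit grey image in the canonical frame
phantom_render_right <- function(p) {
  W <- p$width; H <- p$height
  img <- matrix(p$background_grey, H, W)
  xs <- (0:(W - 1))
  joint_cols <- which(xs >= p$x_medial & xs <= p$x_lateral)
  ys <- (0:(H - 1))
  for (j in joint_cols) {
    x <- xs[j]
    img[ys <= phantom_yf(p, x), j] <- p$femur_grey
    img[ys >= phantom_yt(p, x), j] <- p$tibia_grey
  }
  # wedge stripes (vertical), equal widths across the ROI
  roi <- p$wedge_roi
  k <- length(p$wedge_greys)
  stepw <- floor(roi[3] / k)
  for (i in seq_len(k)) {
    c0 <- roi[1] + (i - 1) * stepw
    cols <- (c0 + 1):(c0 + stepw)
    rows <- (roi[2] + 1):(roi[2] + roi[4])
    img[rows, cols] <- p$wedge_greys[i]
  }
  if (p$noise_sd > 0) {
    img <- with_seed(p$seed, {
      img + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
    })
    img <- pmin(pmax(round(img), 0), 65535)
  }
  img
}

#' Generate a synthetic knee phantom
#'
#' Renders the phantom image, places the 99 landmarks analytically on the
#' rendered bone edges consistently with [knee_region_map()], and returns
#' the closed-form expected measurements. Left-knee phantoms are produced
#' by mirroring the canonical rendering (image, landmarks and wedge ROI)
#' about the vertical midline.
#'
#' @param p a [phantom_params()] object.
#' @return list with `image` (numeric grey matrix), `landmarks`
#'   ([landmark_set()] with the phantom's laterality), `truth` (ground-truth
#'   list), `wedge` (the effective [wedge_spec()], ROI already mirrored for
#'   left knees), and `params`.
#' @export
generate_phantom <- function(p) {
  stopifnot(inherits(p, "phantom_params"))
  img <- phantom_render_right(p)
  pts <- phantom_landmarks_right(p)
  roi <- p$wedge_roi
  if (p$laterality == "left") {
    img <- img[, ncol(img):1, drop = FALSE]
    pts[, 1] <- p$width - 1 - pts[, 1]
    roi[1] <- p$width - roi[1] - roi[3]
  }
  ls <- landmark_set(pts, laterality = p$laterality)
  wedge <- wedge_spec(p$wedge_thicknesses_mm, roi, margin = p$wedge_margin)
  list(image = img, landmarks = ls, truth = phantom_truth(p),
       wedge = wedge, params = p)
}

#' Jitter landmark positions
#'
#' Adds seeded isotropic Gaussian noise to all 99 points, emulating the
#' difference between checked and unchecked automatic point placement.
#' The global RNG state is left untouched.
#'
#' @param ls a [landmark_set()].
#' @param sigma jitter standard deviation in px (>= 0; 0 is the identity).
#' @param seed RNG seed.
#' @return the perturbed `landmark_set`.
#' @export
perturb_landmarks <- function(ls, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(ls)
  out <- ls
  out$points <- with_seed(seed, {
    ls$points + matrix(stats::rnorm(length(ls$points), 0, sigma),
                       nrow(ls$points), 2)
  })
  out
}

#' Named phantom fixture suite
#'
#' Twelve named parameter sets spanning the geometric and photometric
#' conditions the measurement pipeline must handle: parallel joint lines,
#' femoral/tibial tilt, compartment narrowing, tall eminences, a small
#' gap, a wide knee, fine pixel spacing, grey noise, a mirrored left knee
#' and a denser wedge. Stored as generator configurations, never as image
#' binaries.
#'
#' @return named list of [phantom_params()] objects.
#' @export
phantom_suite <- function() {
  list(
    parallel = phantom_params(),
    tilted_femoral = phantom_params(femoral_tilt_deg = 2),
    tilted_tibial = phantom_params(tibial_tilt_deg = 1.5),
    narrowed_medial = phantom_params(femoral_tilt_deg = -2,
                                     gap_center_px = 20),
    narrowed_lateral = phantom_params(femoral_tilt_deg = 2,
                                      gap_center_px = 20),
    tall_eminence = phantom_params(eminence_medial_px = 75,
                                   eminence_lateral_px = 85),
    small_gap = phantom_params(gap_center_px = 12),
    wide_knee = phantom_params(x_medial = 60, x_lateral = 320),
    fine_spacing = phantom_params(pixel_spacing = 0.1),
    noisy = phantom_params(noise_sd = 30, seed = 7L),
    left_knee = phantom_params(laterality = "left"),
    dense_wedge = phantom_params(
      wedge_thicknesses_mm = seq(1.5, 12, by = 1.5),
      wedge_greys = seq(5000, 26000, by = 3000),
      wedge_roi = c(8, 8, 96, 40))
  )
}
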