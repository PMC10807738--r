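# Joint space width: boundary clipping and inscribed-circle fitting.

# exact minimum distance from point p to a polyline (matrix of vertices)
point_poly_dist <- function(p, poly) {
  n <- nrow(poly)
  if (n == 1) return(vnorm(p - poly[1, ]))
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  abx <- b[, 1] - a[, 1]
  aby <- b[, 2] - a[, 2]
  len2 <- abx^2 + aby^2
  apx <- p[1] - a[, 1]
  apy <- p[2] - a[, 2]
  t <- ifelse(len2 > 0, pmin(1, pmax(0, (apx * abx + apy * aby) / len2)), 0)
  dx <- apx - t * abx
  dy <- apy - t * aby
  sqrt(min(dx * dx + dy * dy))
}

# clip a polyline, parameterized by station s along the tibial axis, to
# [lo, hi]; terminal segments are linearly extrapolated when the band
# extends past the annotated span
clip_poly_by_station <- function(pts, s, lo, hi) {
  o <- order(s)
  pts <- pts[o, , drop = FALSE]
  s <- s[o]
  n <- length(s)
  if (n < 2) stop("boundary error: polyline needs at least 2 vertices", call. = FALSE)
  if (s[n] <= lo || s[1] >= hi) {
    stop("boundary error: band entirely outside the annotated polyline span",
         call. = FALSE)
  }
  interp_at <- function(sq) {
    if (sq <= s[1]) {
      i <- 1L
    } else if (sq >= s[n]) {
      i <- n - 1L
    } else {
      i <- max(which(s <= sq))
      if (i >= n) i <- n - 1L
    }
    w <- (sq - s[i]) / (s[i + 1] - s[i])
    pts[i, ] + w * (pts[i + 1, ] - pts[i, ])
  }
  keep <- which(s > lo & s < hi)
  verts <- rbind(interp_at(lo), pts[keep, , drop = FALSE], interp_at(hi))
  extrapolated <- (lo < s[1] - 1e-9) || (hi > s[n] + 1e-9)
  list(poly = verts, extrapolated = extrapolated)
}

#' Clip the joint boundaries of one compartment to its measurement band
#'
#' The upper boundary is the femoral condyle polyline, the lower boundary the
#' anterior tibial plateau polyline of the requested compartment, both
#' clipped between the compartment's outer and inner perpendiculars
#' (stations on the tibial joint line L3). Where the band extends past the
#' annotated point range the terminal segment is extended linearly and the
#' result is flagged as extrapolated.
#'
#' @param ls canonical [landmark_set()].
#' @param fw a [build_framework()] result.
#' @param compartment `"medial"` or `"lateral"`.
#' @param region_map the [knee_region_map()] used to build `fw`.
#' @return an object of class `joint_boundary` with fields `upper`, `lower`
#'   (vertex matrices), `band` (`outer`/`inner` stations), the tibial `axis`,
#'   the perpendicular direction `updir` (unit, toward the femur), and
#'   extrapolation flags.
#' @export
clip_boundaries <- function(ls, fw, compartment = c("medial", "lateral"),
                            region_map = knee_region_map()) {
  compartment <- match.arg(compartment)
  upper_region <- if (compartment == "medial") "femur_medial_condyle" else "femur_lateral_condyle"
  lower_region <- if (compartment == "medial") "tibia_medial_plateau_anterior" else "tibia_lateral_plateau_anterior"
  upper <- region_points(ls, upper_region, region_map)
  lower <- region_points(ls, lower_region, region_map)
  axis <- fw$tibial_axis
  stat <- function(pts) {
    as.numeric((pts[, 1] - axis$point[1]) * axis$dir[1] +
               (pts[, 2] - axis$point[2]) * axis$dir[2])
  }
  band <- fw$bands[[compartment]]$tibia
  lo <- min(band$outer, band$inner)
  hi <- max(band$outer, band$inner)
  cu <- clip_poly_by_station(upper, stat(upper), lo, hi)
  cl <- clip_poly_by_station(lower, stat(lower), lo, hi)
  structure(
    list(compartment = compartment, upper = cu$poly, lower = cl$poly,
         band = band, axis = axis, updir = fw$n3_femur,
         extrapolated_upper = cu$extrapolated,
         extrapolated_lower = cl$extrapolated),
    class = "joint_boundary"
  )
}

# station/offset coordinates of polyline vertices relative to the boundary
# axis: s along the axis, u along updir
poly_su <- function(boundary, poly) {
  ax <- boundary$axis
  rel_x <- poly[, 1] - ax$point[1]
  rel_y <- poly[, 2] - ax$point[2]
  list(s = rel_x * ax$dir[1] + rel_y * ax$dir[2],
       u = rel_x * boundary$updir[1] + rel_y * boundary$updir[2])
}

#' Largest circle inscribed in the joint space at a station
#'
#' The circle center is constrained to the perpendicular of the tibial joint
#' line at the given station, so the diameter is a local joint space width
#' at a defined location. The radius of a candidate center is the smaller of
#' its exact distances to the upper (femoral) and lower (tibial) boundary
#' polylines; the center position along the perpendicular is optimized by a
#' coarse scan followed by golden-section search to 1e-4 px.
#'
#' When the boundaries cross at the station (negative gap), a zero-radius
#' circle with a `crossing` flag is returned, never a negative radius.
#'
#' @param boundary a [clip_boundaries()] result.
#' @param station arc length along the tibial axis, inside the band.
#' @return a list with `center`, `radius`, `diameter`, `station`,
#'   `compartment`, `crossing`.
#' @export
inscribed_circle_at <- function(boundary, station) {
  ax <- boundary$axis
  u <- boundary$updir
  p0 <- ax$point + station * ax$dir
  su_up <- poly_su(boundary, boundary$upper)
  su_lo <- poly_su(boundary, boundary$lower)
  u_up <- stats::approx(su_up$s, su_up$u, xout = station, rule = 2, ties = "ordered")$y
  u_lo <- stats::approx(su_lo$s, su_lo$u, xout = station, rule = 2, ties = "ordered")$y
  if (u_up <= u_lo) {
    return(list(center = p0 + 0.5 * (u_up + u_lo) * u, radius = 0,
                diameter = 0, station = station,
                compartment = boundary$compartment, crossing = TRUE))
  }
  radius_at <- function(t) {
    cen <- p0 + t * u
    min(point_poly_dist(cen, boundary$upper),
        point_poly_dist(cen, boundary$lower))
  }
  tgrid <- seq(u_lo, u_up, length.out = 33)
  rg <- vapply(tgrid, radius_at, numeric(1))
  k <- which.max(rg)
  a <- tgrid[max(1, k - 1)]
  b <- tgrid[min(length(tgrid), k + 1)]
  # golden-section maximization on [a, b]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- radius_at(x1)
  f2 <- radius_at(x2)
  while (b - a > 1e-6) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- radius_at(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- radius_at(x1)
    }
  }
  tbest <- (a + b) / 2
  r <- radius_at(tbest)
  list(center = p0 + tbest * u, radius = r, diameter = 2 * r,
       station = station, compartment = boundary$compartment, crossing = FALSE)
}

#' Measure mean medial/lateral and minimal joint space width
#'
#' Fits 30 intra-articular inscribed circles (by default 15 per compartment,
#' at stations placed at the midpoints of a uniform subdivision of the band
#' between the outer and inner perpendicular: `outer + (i + 0.5)/15 *
#' (inner - outer)`). Circle diameters are the local joint space widths; the
#' per-compartment mean JSW is the arithmetic mean of its diameters times
#' the pixel spacing, and the minimal JSW is the global minimum diameter at
#' either side.
#'
#' @param ls canonical [landmark_set()].
#' @param fw a [build_framework()] result.
#' @param pixel_spacing pixel spacing in mm/px (> 0).
#' @param region_map the [knee_region_map()] used to build `fw`.
#' @param n_per_compartment circles per compartment (default 15).
#' @return an object of class `jsw_result`: per-circle table `circles`
#'   (compartment, station, center, radius/diameter in px and mm, crossing
#'   flag), `mean_medial_jsw_mm`, `mean_lateral_jsw_mm`, `minimal_jsw_mm`,
#'   `minimal_jsw_compartment`, `pixel_spacing`, extrapolation/crossing
#'   quality flags.
#' @export
measure_jsw <- function(ls, fw, pixel_spacing,
                        region_map = knee_region_map(),
                        n_per_compartment = 15L) {
  stopifnot(pixel_spacing > 0, n_per_compartment >= 1)
  rows <- list()
  extrapolated <- FALSE
  for (comp in c("medial", "lateral")) {
    boundary <- clip_boundaries(ls, fw, comp, region_map)
    extrapolated <- extrapolated || boundary$extrapolated_upper ||
      boundary$extrapolated_lower
    band <- boundary$band
    i <- seq_len(n_per_compartment)
    stations <- band$outer + (i - 0.5) / n_per_compartment * (band$inner - band$outer)
    for (s in stations) {
      circ <- inscribed_circle_at(boundary, s)
      rows[[length(rows) + 1]] <- data.frame(
        compartment = comp, station_px = circ$station,
        center_x = circ$center[1], center_y = circ$center[2],
        radius_px = circ$radius, diameter_px = circ$diameter,
        diameter_mm = circ$diameter * pixel_spacing,
        crossing = circ$crossing
      )
    }
  }
  circles <- do.call(rbind, rows)
  med <- circles$diameter_mm[circles$compartment == "medial"]
  lat <- circles$diameter_mm[circles$compartment == "lateral"]
  kmin <- which.min(circles$diameter_mm)
  structure(
    list(circles = circles,
         mean_medial_jsw_mm = mean(med),
         mean_lateral_jsw_mm = mean(lat),
         minimal_jsw_mm = circles$diameter_mm[kmin],
         minimal_jsw_compartment = circles$compartment[kmin],
         pixel_spacing = pixel_spacing,
         n_circles = nrow(circles),
         extrapolated = extrapolated,
         crossing_stations = circles$station_px[circles$crossing]),
    class = "jsw_result"
  )
}

#' @export
print.jsw_result <- function(x, ...) {
  cat(sprintf("<jsw_result> %d circles | mean medial %.3f mm, mean lateral %.3f mm, minimal %.3f mm (%s)\n",
              x$n_circles, x$mean_medial_jsw_mm, x$mean_lateral_jsw_mm,
              x$minimal_jsw_mm, x$minimal_jsw_compartment))
  if (length(x$crossing_stations)) {
    cat(sprintf("  warning: boundary crossing at %d station(s)\n",
                length(x$crossing_stations)))
  }
  invisible(x)
}

#' Export per-circle JSW rows to CSV
#'
#' One row per inscribed circle plus a summary row.
#'
#' @param jsw a `jsw_result`.
#' @param path output CSV path.
#' @export
write_jsw_csv <- function(jsw, path) {
  df <- jsw$circles
  df$station_mm <- df$station_px * jsw$pixel_spacing
  summary_row <- data.frame(
    compartment = "summary", station_px = NA, center_x = NA, center_y = NA,
    radius_px = NA, diameter_px = NA,
    diameter_mm = jsw$minimal_jsw_mm, crossing = FALSE,
    station_mm = NA
  )
  utils::write.csv(rbind(df, summary_row), path, row.names = FALSE)
  invisible(path)
}
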