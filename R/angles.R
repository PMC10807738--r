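# Joint line convergence angle and tibial eminence heights.

#' Joint line convergence angle (JLCA)
#'
#' The angle between the distal femoral joint line (L2) and the proximal
#' tibial joint line. Two tibial-line definitions are supported:
#' `"framework_l3"` (default) uses the framework's supporting line L3;
#' `"landmarks_7_26"` uses the clinical tibial line through landmark points
#' 7 and 26.
#'
#' The magnitude is `acos(|d2 . d3|)` in degrees. The sign convention is a
#' package choice for interpretability: positive when the joint space
#' narrows toward the lateral side (computed from the cross product of the
#' two directions oriented lateral-to-medial in the canonical frame); the
#' unsigned magnitude is reported alongside. Values beyond 45 degrees are
#' flagged as implausible but never clamped.
#'
#' @param fw a [build_framework()] result.
#' @param ls canonical [landmark_set()] (required for `"landmarks_7_26"`).
#' @param method `"framework_l3"` or `"landmarks_7_26"`.
#' @param region_map a [knee_region_map()].
#' @return list with `jlca_deg` (signed), `jlca_abs_deg`, `method`,
#'   `flagged`.
#' @export
jlca <- function(fw, ls = NULL, method = c("framework_l3", "landmarks_7_26"),
                 region_map = knee_region_map()) {
  method <- match.arg(method)
  d2 <- fw$L2$dir
  if (method == "framework_l3") {
    d3 <- fw$L3$dir
  } else {
    if (is.null(ls)) stop("landmark set required for landmarks_7_26", call. = FALSE)
    pr <- region_points(ls, "clinical_tibial_line_points", region_map)
    v <- as.numeric(pr[2, ] - pr[1, ])
    if (vnorm(v) < 1e-9) stop("geometry error: points 7 and 26 coincide", call. = FALSE)
    d3 <- unit_vec(v)
  }
  ang <- rad2deg(acos(min(1, abs(sum(d2 * d3)))))
  # orient both directions lateral-to-medial (A -> B runs lateral to medial)
  lat2med <- fw$tibial_axis$dir
  o2 <- if (sum(d2 * lat2med) < 0) -d2 else d2
  o3 <- if (sum(d3 * lat2med) < 0) -d3 else d3
  s <- cross2(o3, o2)
  signed <- if (abs(s) < 1e-15) ang else sign(s) * ang
  list(jlca_deg = signed, jlca_abs_deg = ang, method = method,
       flagged = ang > 45)
}

#' Tibial eminence heights
#'
#' Landmark points 15 and 19 mark the most proximal points of the medial
#' and lateral intercondylar eminences. Heights are the unsigned
#' perpendicular distances of those points to the tibial joint line L3,
#' converted to mm. Because the shape model does not fix which of the two
#' indices is medial, assignment is by canonical x position (smaller x =
#' medial); the rule applied is recorded in the result.
#'
#' @param ls canonical [landmark_set()].
#' @param fw a [build_framework()] result.
#' @param pixel_spacing mm per pixel (> 0).
#' @param region_map a [knee_region_map()].
#' @return list with `medial_mm`, `lateral_mm`, `assignment` (named index
#'   vector), `rule`.
#' @export
eminence_heights <- function(ls, fw, pixel_spacing,
                             region_map = knee_region_map()) {
  stopifnot(pixel_spacing > 0)
  idx <- region_map$eminence_points
  pts <- ls$points[idx, , drop = FALSE]
  d <- abs(line_signed_dist(fw$L3, pts)) * pixel_spacing
  med <- which.min(pts[, 1])
  lat <- if (med == 1L) 2L else 1L
  list(medial_mm = d[med], lateral_mm = d[lat],
       assignment = c(medial = idx[med], lateral = idx[lat]),
       rule = "smaller canonical x = medial")
}
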