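# Step-wedge densitometric calibration and subchondral intensity sampling.
#
# Images are numeric matrices (rows = y, cols = x) in MONOCHROME2 convention:
# higher grey = more attenuation, so grey increases with aluminum thickness.

#' Describe the aluminum step-wedge phantom
#'
#' @param thicknesses_mm step thicknesses in mm of aluminum, strictly
#'   increasing, at least 2 steps.
#' @param roi region of interest containing the wedge, `c(x, y, w, h)` in
#'   pixels (0-based corner).
#' @param margin per-step erosion margin in pixels applied before sampling,
#'   to keep step-edge penumbra out of the means.
#' @param orientation `"vertical"` when the steps are vertical stripes
#'   (profile taken over columns), `"horizontal"` for horizontal stripes.
#' @return an object of class `wedge_spec`.
#' @export
wedge_spec <- function(thicknesses_mm, roi, margin = 2L,
                       orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (length(thicknesses_mm) < 2) stop("wedge needs at least 2 steps", call. = FALSE)
  if (any(diff(thicknesses_mm) <= 0)) {
    stop("wedge step thicknesses must be strictly increasing", call. = FALSE)
  }
  roi <- as.numeric(roi)
  if (length(roi) != 4 || any(roi[3:4] <= 0)) {
    stop("roi must be c(x, y, w, h) with positive size", call. = FALSE)
  }
  structure(list(thicknesses_mm = as.numeric(thicknesses_mm), roi = roi,
                 margin = as.integer(margin), orientation = orientation),
            class = "wedge_spec")
}

#' Segment the wedge ROI into per-step pixel regions
#'
#' Within the ROI the mean grey profile across the stripe direction is
#' clustered by 1D k-means (k = number of steps, deterministic
#' evenly-spaced initial centers). The resulting contiguous bands are eroded
#' by the sampling margin on every side and returned in spatial order along
#' the profile axis; step thicknesses are assumed to ascend along that axis,
#' so grey order and spatial order coincide for a well-formed wedge.
#'
#' @param image numeric grey matrix.
#' @param spec a [wedge_spec()].
#' @return list of step regions, each `list(rows, cols, mean_grey)`, class
#'   `wedge_regions`.
#' @export
detect_wedge <- function(image, spec) {
  k <- length(spec$thicknesses_mm)
  x <- spec$roi[1]; y <- spec$roi[2]; w <- spec$roi[3]; h <- spec$roi[4]
  nr <- nrow(image); nc <- ncol(image)
  cols <- (x + 1):(x + w)
  rows <- (y + 1):(y + h)
  if (x < 0 || y < 0 || x + w > nc || y + h > nr) {
    stop("wedge ROI outside image", call. = FALSE)
  }
  sub <- image[rows, cols, drop = FALSE]
  profile <- if (spec$orientation == "vertical") colMeans(sub) else rowMeans(sub)
  rng <- range(profile)
  if (diff(rng) < 1e-9) {
    stop("wedge detection failed: flat intensity profile; supply a manual ROI",
         call. = FALSE)
  }
  centers <- matrix(seq(rng[1], rng[2], length.out = k))
  km <- tryCatch(
    stats::kmeans(matrix(profile), centers = centers, iter.max = 100),
    error = function(e) stop("wedge detection failed: ", conditionMessage(e),
                             "; supply a manual ROI", call. = FALSE)
  )
  # order cluster labels by center grey, then require k contiguous bands
  rank_of <- rank(km$centers[, 1])
  labels <- rank_of[km$cluster]
  if (length(unique(labels)) < k ||
      min(diff(sort(km$centers[, 1]))) < 1e-9) {
    stop("wedge detection failed: fewer distinct bands than steps; supply a manual ROI",
         call. = FALSE)
  }
  runs <- rle(labels)
  if (length(runs$lengths) != k) {
    # single-position misassignments: smooth once with a running median
    labels <- as.integer(stats::runmed(labels, 3))
    runs <- rle(labels)
  }
  if (length(runs$lengths) != k) {
    stop("wedge detection failed: step bands are not contiguous; supply a manual ROI",
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  m <- spec$margin
  regions <- vector("list", k)
  for (i in seq_len(k)) {
    lo <- starts[i] + m
    hi <- ends[i] - m
    if (lo > hi) {
      stop("wedge detection failed: a step band is narrower than twice the margin",
           call. = FALSE)
    }
    if (spec$orientation == "vertical") {
      rcols <- cols[lo:hi]
      rrows <- rows[(1 + m):(h - m)]
    } else {
      rrows <- rows[lo:hi]
      rcols <- cols[(1 + m):(w - m)]
    }
    regions[[i]] <- list(rows = rrows, cols = rcols,
                         mean_grey = mean(image[rrows, rcols]),
                         label = runs$values[i])
  }
  # regions stay in spatial order along the profile axis; for a well-formed
  # wedge (thickness ascending along the axis) this equals grey order, and
  # build_calibration uses the comparison to catch wrong ROIs and inverted
  # photometric interpretation
  structure(regions, class = "wedge_regions")
}

#' Build the grey-value to mm-aluminum calibration curve
#'
#' Knot grey values are the mean greys of the eroded step regions; knot
#' mm-Al values are the specified step thicknesses. Evaluation is piecewise
#' linear between knots and clamped at the ends. A non-monotone grey
#' sequence signals a wrong ROI or inverted photometric interpretation and
#' is an error.
#'
#' @param regions a [detect_wedge()] result (one region per step, in step
#'   order after grey sorting).
#' @param image numeric grey matrix.
#' @param spec the [wedge_spec()].
#' @return an object of class `calibration_curve` with knot vectors `grey`
#'   and `mmal`.
#' @export
build_calibration <- function(regions, image, spec) {
  k <- length(spec$thicknesses_mm)
  if (length(regions) != k) stop("need one wedge region per step", call. = FALSE)
  greys <- vapply(regions, function(r) {
    if (!length(r$rows) || !length(r$cols)) stop("empty wedge step mask", call. = FALSE)
    mean(image[r$rows, r$cols])
  }, numeric(1))
  if (any(diff(greys) <= 0)) {
    stop("non-monotone wedge greys: check ROI and photometric interpretation",
         call. = FALSE)
  }
  structure(list(grey = greys, mmal = spec$thicknesses_mm),
            class = "calibration_curve")
}

#' Convert grey values to mm aluminum equivalence
#'
#' Piecewise-linear interpolation between calibration knots; values outside
#' the knot range are clamped to the end knots and flagged via the
#' `"clamped"` attribute of the result.
#'
#' @param object a `calibration_curve`.
#' @param grey numeric grey values.
#' @param ... unused.
#' @return numeric mmAl values with logical attribute `clamped`.
#' @export
predict.calibration_curve <- function(object, grey, ...) {
  out <- stats::approx(object$grey, object$mmal, xout = grey, rule = 2,
                       ties = "ordered")$y
  attr(out, "clamped") <- grey < min(object$grey) | grey > max(object$grey)
  out
}

#' Place the four subchondral sampling circles of one bone-compartment
#'
#' Four circles of diameter `S/20` (`S = AB` for tibial circles, `CD` for
#' femoral) are centered on four perpendiculars to the bone's joint line
#' (L3 for the tibia, L2 for the femur), anchored at the compartment's outer
#' perpendicular and marching inward at mutual spacing `S/20`. Each circle
#' is tangent to the joint line on the bone side (below L3 for the tibia,
#' above L2 for the femur) so it samples subchondral bone and never the
#' joint space.
#'
#' @param fw a [build_framework()] result.
#' @param compartment `"medial"` or `"lateral"`.
#' @param bone `"tibia"` or `"femur"`.
#' @param image_dim optional `c(nrow, ncol)`; when given, circles extending
#'   outside the image raise a placement error naming the station.
#' @return data.frame with one row per circle: `station`, `cx`, `cy`, `r`,
#'   `bone`, `compartment`.
#' @export
place_subchondral_circles <- function(fw, compartment = c("medial", "lateral"),
                                      bone = c("tibia", "femur"),
                                      image_dim = NULL) {
  compartment <- match.arg(compartment)
  bone <- match.arg(bone)
  S <- if (bone == "tibia") fw$AB else fw$CD
  axis <- if (bone == "tibia") fw$tibial_axis else fw$femoral_axis
  band <- fw$bands[[compartment]][[bone]]
  sgn <- sign(band$inner - band$outer)
  stations <- band$outer + (0:3) * (S / 20) * sgn
  r <- S / 40
  # into-bone direction: opposite the joint space
  n_bone <- if (bone == "tibia") -fw$n3_femur else -fw$n2_tibia
  centers <- t(vapply(stations, function(s) {
    axis$point + s * axis$dir + r * n_bone
  }, numeric(2)))
  if (!is.null(image_dim)) {
    bad <- centers[, 1] - r < 0 | centers[, 1] + r > image_dim[2] - 1 |
      centers[, 2] - r < 0 | centers[, 2] + r > image_dim[1] - 1
    if (any(bad)) {
      stop(sprintf("subchondral circle outside image at station %.2f px",
                   stations[which(bad)[1]]), call. = FALSE)
    }
  }
  data.frame(station = stations, cx = centers[, 1], cy = centers[, 2],
             r = r, bone = bone, compartment = compartment)
}

# mean grey over a circle mask; pixel membership by the center-in rule
# (pixel center within the radius), pixel (row i, col j) center = (j-1, i-1)
circle_mean_grey <- function(image, cx, cy, r) {
  nr <- nrow(image); nc <- ncol(image)
  jmin <- max(1L, as.integer(ceiling(cx - r + 1 - 1e-9)))
  jmax <- min(nc, as.integer(floor(cx + r + 1 + 1e-9)))
  imin <- max(1L, as.integer(ceiling(cy - r + 1 - 1e-9)))
  imax <- min(nr, as.integer(floor(cy + r + 1 + 1e-9)))
  if (jmin > jmax || imin > imax) stop("empty circle mask", call. = FALSE)
  xs <- (jmin:jmax) - 1
  ys <- (imin:imax) - 1
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  if (!any(inside)) stop("empty circle mask", call. = FALSE)
  sub <- image[imin:imax, jmin:jmax, drop = FALSE]
  mean(sub[inside])
}

#' Measure calibrated subchondral bone intensities
#'
#' For each bone (femur, tibia) and compartment (medial, lateral), the mean
#' grey within each of the four subchondral circles is converted to mmAl via
#' the calibration curve; the group value is the mean of its four circle
#' values.
#'
#' @param image numeric grey matrix (MONOCHROME2 convention).
#' @param fw a [build_framework()] result.
#' @param calib a [build_calibration()] curve.
#' @return object of class `subchondral_intensities`: `circles` data.frame
#'   (one row per circle with grey and mmAl) and `summary` data.frame (bone,
#'   compartment, `mean_mmal`), plus a `clamped` flag when any circle grey
#'   fell outside the calibration range.
#' @export
measure_intensities <- function(image, fw, calib) {
  groups <- expand.grid(bone = c("tibia", "femur"),
                        compartment = c("medial", "lateral"),
                        stringsAsFactors = FALSE)
  circ_rows <- list()
  sum_rows <- list()
  clamped <- FALSE
  for (g in seq_len(nrow(groups))) {
    circles <- place_subchondral_circles(fw, groups$compartment[g],
                                         groups$bone[g], dim(image))
    grey <- vapply(seq_len(nrow(circles)), function(i) {
      circle_mean_grey(image, circles$cx[i], circles$cy[i], circles$r[i])
    }, numeric(1))
    mmal <- predict(calib, grey)
    clamped <- clamped || any(attr(mmal, "clamped"))
    circles$mean_grey <- grey
    circles$mmal <- as.numeric(mmal)
    circ_rows[[g]] <- circles
    sum_rows[[g]] <- data.frame(bone = groups$bone[g],
                                compartment = groups$compartment[g],
                                mean_mmal = mean(as.numeric(mmal)))
  }
  structure(list(circles = do.call(rbind, circ_rows),
                 summary = do.call(rbind, sum_rows),
                 clamped = clamped),
            class = "subchondral_intensities")
}

#' @export
print.subchondral_intensities <- function(x, ...) {
  cat("<subchondral_intensities> mean mmAl per bone-compartment:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
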