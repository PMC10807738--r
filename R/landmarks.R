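#' The 99-point knee landmark set
#'
#' Wraps the 99 bone-contour landmarks produced by a statistical shape-model
#' annotation tool for a posteroanterior knee radiograph: distal femur,
#' patella and proximal tibia. Points are stored in file order; all
#' user-facing indexing is 1-based (point 1 is the first point in the file).
#' Coordinates are pixels in the image frame: x rightward, y downward,
#' 0-based pixel centers (pixel `[row r, col c]` of the image matrix has
#' center `(c - 1, r - 1)`).
#'
#' @param points numeric n x 2 matrix of (x, y) coordinates.
#' @param laterality `"left"`, `"right"` or `"unknown"` — which knee the
#'   radiograph shows.
#' @param n_expected expected number of points (99 for the knee model).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, laterality = c("unknown", "left", "right"),
                         n_expected = 99L) {
  laterality <- match.arg(laterality)
  points <- rbind_pts(points)
  if (nrow(points) != n_expected) {
    stop(sprintf("expected %d points, found %d", n_expected, nrow(points)),
         call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("landmark coordinates must all be finite", call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  structure(
    list(points = points, laterality = laterality,
         canonical = FALSE, mirrored = FALSE),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points, laterality %s%s\n",
              nrow(x$points), x$laterality,
              if (x$canonical) ", canonical" else ""))
  invisible(x)
}

#' Anatomical region index map for the 99-point knee model
#'
#' Names the landmark index ranges used by the measurement framework. Ranges
#' are inclusive and 1-based. The lateral tibial plateau range is 20–25 by
#' default with a 20–26 variant selectable; contour regions overlap at the
#' plateau/shaft corners by construction of the shape model.
#'
#' @param lateral_plateau `"20_25"` (default) or `"20_26"`.
#' @return a named list of integer index vectors, class `knee_region_map`.
#' @export
knee_region_map <- function(lateral_plateau = c("20_25", "20_26")) {
  lateral_plateau <- match.arg(lateral_plateau)
  lat_pl <- if (lateral_plateau == "20_25") 20:25 else 20:26
  structure(
    list(
      tibia_medial_curve = 2:7,
      tibia_medial_plateau_anterior = 9:13,
      eminence_points = c(15L, 19L),
      tibia_lateral_plateau_anterior = lat_pl,
      tibia_lateral_curve = 24:32,
      tibia_posterior_medial_plateau = c(9L, 13L, 35L, 36L),
      femur_medial_curve = 58:64,
      femur_medial_condyle = 63:68,
      femur_lateral_condyle = 70:75,
      femur_lateral_curve = c(74:80, 90:98),
      clinical_tibial_line_points = c(7L, 26L)
    ),
    lateral_plateau = lateral_plateau,
    class = "knee_region_map"
  )
}

#' Export a region map as JSON for audit
#'
#' @param map a `knee_region_map`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
region_map_json <- function(map, path = NULL) {
  js <- jsonlite::toJSON(unclass(map), auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Extract the points of a named anatomical region
#'
#' @param ls a `landmark_set`.
#' @param region_name one of the names in [knee_region_map()].
#' @param region_map the region map to use.
#' @return matrix of points in index order.
#' @export
region_points <- function(ls, region_name, region_map = knee_region_map()) {
  if (!region_name %in% names(region_map)) {
    stop(sprintf("unknown region '%s'; valid regions: %s", region_name,
                 paste(names(region_map), collapse = ", ")), call. = FALSE)
  }
  ls$points[region_map[[region_name]], , drop = FALSE]
}

#' Read a landmark point-list file
#'
#' Parses the plain-text point-list dialect emitted by shape-model annotation
#' tools: a `version:` line, an `n_points:` line (with or without a space
#' after the colon), then one `x y` pair per line between `{` and `}`.
#'
#' @param path file path.
#' @param expected_n expected point count (default 99).
#' @param laterality laterality to record on the returned set.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, expected_n = 99L, laterality = "unknown") {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  np_line <- grep("^\\s*n_points\\s*:", lines)
  if (!length(np_line)) stop("missing n_points header line", call. = FALSE)
  n_declared <- suppressWarnings(
    as.integer(sub("^\\s*n_points\\s*:\\s*", "", lines[np_line[1]]))
  )
  if (is.na(n_declared)) stop("unparseable n_points header", call. = FALSE)
  if (n_declared != expected_n) {
    stop(sprintf("expected %d points, found %d", expected_n, n_declared),
         call. = FALSE)
  }
  open_i <- grep("^\\s*\\{", lines)
  close_i <- grep("^\\s*\\}", lines)
  if (!length(open_i) || !length(close_i)) {
    stop("missing braced coordinate block", call. = FALSE)
  }
  body <- lines[(open_i[1] + 1):(close_i[length(close_i)] - 1)]
  body_idx <- which(nzchar(trimws(body)))
  pts <- matrix(NA_real_, length(body_idx), 2)
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    toks <- strsplit(trimws(body[ln]), "\\s+")[[1]]
    xy <- suppressWarnings(as.numeric(toks[1:2]))
    if (length(toks) < 2 || anyNA(xy)) {
      stop(sprintf("non-numeric coordinate at line %d of the point block",
                   open_i[1] + ln), call. = FALSE)
    }
    pts[k, ] <- xy
  }
  if (nrow(pts) != expected_n) {
    stop(sprintf("expected %d points, found %d", expected_n, nrow(pts)),
         call. = FALSE)
  }
  landmark_set(pts, laterality = laterality, n_expected = expected_n)
}

#' Write a landmark set in point-list format
#'
#' Coordinates are written with enough precision to round-trip to 1e-6 px.
#'
#' @param ls a `landmark_set`.
#' @param path output path.
#' @export
write_landmarks <- function(ls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("version: 1",
               sprintf("n_points: %d", nrow(ls$points)),
               "{"), con)
  writeLines(sprintf("%.10g %.10g", ls$points[, 1], ls$points[, 2]), con)
  writeLines("}", con)
  invisible(path)
}

#' Canonicalize a landmark set to a right-knee geometric convention
#'
#' Left knees are mirrored about the vertical image midline so that the
#' lateral compartment lies on the +x side for every downstream computation;
#' right knees pass through unchanged. With 0-based pixel-center coordinates
#' the mirror of `x` in an image of width `W` is `W - 1 - x`. The operation
#' is idempotent and preserves all inter-point distances.
#'
#' @param ls a `landmark_set` with known laterality.
#' @param image_width image width in pixels.
#' @return the canonical `landmark_set` (with `canonical = TRUE` and the
#'   `mirrored` flag recorded).
#' @export
canonicalize <- function(ls, image_width) {
  if (isTRUE(ls$canonical)) return(ls)
  if (ls$laterality == "unknown") {
    stop("laterality unknown: supply it in the run configuration", call. = FALSE)
  }
  out <- ls
  if (ls$laterality == "left") {
    out$points[, 1] <- image_width - 1 - out$points[, 1]
    out$mirrored <- TRUE
  }
  out$canonical <- TRUE
  out
}
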