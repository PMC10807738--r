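#' Construct a 2D line
#'
#' Lines live in the image coordinate frame (x right, y down, pixel units).
#' The direction is normalized to unit length and canonicalized to the upper
#' half-plane angle range `[0, pi)` so that equal lines compare equal.
#' An optional `normal` records which side of the line is the "contact" side
#' for supporting lines.
#'
#' @param point numeric length-2, any point on the line.
#' @param dir numeric length-2 direction vector (need not be unit length).
#' @param normal optional numeric length-2 vector identifying the contact
#'   half-plane; normalized to unit length.
#' @param canonicalize canonicalize the direction to the `[0, pi)` angle
#'   range? Set `FALSE` for oriented axes where stations must be measured in
#'   the direction given (e.g. from corner A toward corner B).
#' @return an object of class `kline` with fields `point`, `dir`, `normal`.
#' @export
new_line <- function(point, dir, normal = NULL, canonicalize = TRUE) {
  d <- unit_vec(as.numeric(dir))
  if (canonicalize && (d[2] < 0 || (d[2] == 0 && d[1] < 0))) d <- -d
  structure(
    list(point = as.numeric(point), dir = d,
         normal = if (!is.null(normal)) unit_vec(as.numeric(normal))),
    class = "kline"
  )
}

#' @export
print.kline <- function(x, ...) {
  cat(sprintf("<line> through (%.3f, %.3f) dir (%.4f, %.4f)\n",
              x$point[1], x$point[2], x$dir[1], x$dir[2]))
  invisible(x)
}

#' Signed distances from points to a line
#'
#' Positive on the side of the line's normal (the contact side when the line
#' is a supporting line). Falls back to the counter-clockwise normal of the
#' direction when the line carries no normal.
#'
#' @param line a `kline`.
#' @param pts numeric matrix (n x 2) or length-2 vector.
#' @return numeric vector of signed distances in pixels.
#' @export
line_signed_dist <- function(line, pts) {
  n <- line$normal %||% rot90ccw(line$dir)
  pts <- rbind_pts(pts)
  as.numeric((pts[, 1] - line$point[1]) * n[1] + (pts[, 2] - line$point[2]) * n[2])
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) matrix(pts, ncol = 2) else as.matrix(pts)
}

#' Intersection point of two lines
#'
#' @param l1,l2 `kline` objects.
#' @return numeric length-2 point, or `NULL` when the lines are parallel.
#' @export
line_intersect <- function(l1, l2) {
  d <- cross2(l1$dir, l2$dir)
  if (abs(d) < 1e-12) return(NULL)
  dp <- l2$point - l1$point
  t <- cross2(dp, l2$dir) / d
  l1$point + t * l1$dir
}

#' Supporting (tangent) line of a point set
#'
#' Returns the unique line touching the point set such that every point lies
#' on or inside the half-plane opposite `contact_side`: among convex-hull
#' edges it is the one whose outward normal has maximal dot product with
#' `contact_side`. This is the geometric realization of "a line touching the
#' curves" used to place the four framework lines around the knee joint.
#'
#' Ties between hull edges with equal normal alignment are broken by the edge
#' touching more input points, then by the smaller index of the first
#' touching point, so reruns are bit-identical.
#'
#' @param pts numeric matrix (n x 2) of points, n >= 2, not all coincident.
#' @param contact_side numeric length-2 direction pointing toward the free
#'   side the line should face (e.g. `c(0, 1)` for a line supporting the set
#'   from below in image coordinates).
#' @return a `kline` whose `normal` points toward `contact_side`.
#' @export
supporting_line <- function(pts, contact_side) {
  pts <- rbind_pts(pts)
  if (nrow(pts) < 2) stop("supporting_line needs at least 2 points", call. = FALSE)
  if (!all(is.finite(pts))) stop("non-finite coordinates in point set", call. = FALSE)
  contact <- unit_vec(as.numeric(contact_side))
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  scale <- max(1, max(abs(centered)))
  if (max(abs(centered)) < 1e-9) {
    stop("degenerate geometry: all points coincident", call. = FALSE)
  }
  sv <- svd(centered, nu = 0, nv = 2)
  if (sv$d[2] < 1e-9 * scale) {
    # collinear set: the line through the two extreme points
    dirv <- sv$v[, 1]
    t <- as.numeric(centered %*% dirv)
    p0 <- pts[which.min(t), ]
    d <- unit_vec(pts[which.max(t), ] - p0)
    n <- rot90ccw(d)
    if (sum(n * contact) < 0) n <- -n
    return(new_line(p0, d, n))
  }
  hull <- grDevices::chull(pts)
  m <- length(hull)
  best <- NULL
  tol <- 1e-9 * scale
  for (e in seq_len(m)) {
    i <- hull[e]
    j <- hull[if (e == m) 1L else e + 1L]
    d <- unit_vec(pts[j, ] - pts[i, ])
    n <- rot90ccw(d)
    # orient outward: away from the hull centroid
    if (sum(n * (ctr - pts[i, ])) > 0) n <- -n
    score <- sum(n * contact)
    sd_all <- (pts[, 1] - pts[i, 1]) * n[1] + (pts[, 2] - pts[i, 2]) * n[2]
    touches <- which(abs(sd_all) <= tol)
    cand <- list(p = pts[i, ], d = d, n = n, score = score,
                 ntouch = length(touches),
                 first = if (length(touches)) min(touches) else Inf)
    if (is.null(best) ||
        cand$score > best$score + 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         (cand$ntouch > best$ntouch ||
          (cand$ntouch == best$ntouch && cand$first < best$first)))) {
      best <- cand
    }
  }
  new_line(best$p, best$d, best$n)
}

#' Perpendicular to a line at an arc-length station
#'
#' @param line a `kline`; stations are measured from `line$point` along
#'   `line$dir`.
#' @param station arc length in pixels.
#' @return a `kline` through the station point, orthogonal to `line`.
#' @export
perpendicular_at <- function(line, station) {
  p <- line$point + station * line$dir
  new_line(p, rot90ccw(line$dir))
}
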