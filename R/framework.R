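#' Build the four-line measurement framework
#'
#' Places the framework around the tibiofemoral joint from a canonical
#' landmark set:
#'
#' * `L1` — supporting line of the lateral bone contours (tibial lateral
#'   curve plus femoral lateral curve) from the lateral (+x) side;
#' * `L4` — supporting line of the medial contours from the medial (-x) side;
#' * `L2` — the femoral joint line: supporting line of the medial and lateral
#'   condyle points from the distal (+y) side;
#' * `L3` — the tibial joint line: supporting line of the anterior medial and
#'   lateral plateau points from the proximal (-y) side.
#'
#' Corner points are the intersections `A = L3 ∩ L1` (lateral tibial),
#' `B = L3 ∩ L4` (medial tibial), `C = L2 ∩ L1` (lateral femoral) and
#' `D = L2 ∩ L4` (medial femoral). Scale lengths `AB` and `CD` are the corner
#' distances in pixels. For each compartment the outer perpendicular station
#' sits `2/15 * AB` (tibial, on L3) or `2/15 * CD` (femoral, on L2) inward
#' from its corner, and the inner perpendicular a further `3/20` of the same
#' scale length inward; these bands bound all joint-space and subchondral
#' measurements.
#'
#' Stations are arc lengths along the oriented tibial axis (A toward B) or
#' femoral axis (C toward D). The whole construction is equivariant under
#' rigid motions of the landmark set and scales linearly under similarity
#' transforms.
#'
#' @param ls a canonical [landmark_set()] (see [canonicalize()]).
#' @param region_map a [knee_region_map()].
#' @return an object of class `knee_framework` with fields `L1`..`L4`,
#'   corners `A`..`D`, scale lengths `AB`/`CD`, oriented axes
#'   `tibial_axis`/`femoral_axis`, the L3 normal toward the femur
#'   (`n3_femur`), the L2 normal toward the tibia (`n2_tibia`), and
#'   `bands[[compartment]][[bone]]` station pairs (`outer`, `inner`).
#' @export
build_framework <- function(ls, region_map = knee_region_map()) {
  lat_curve <- rbind(region_points(ls, "tibia_lateral_curve", region_map),
                     region_points(ls, "femur_lateral_curve", region_map))
  med_curve <- rbind(region_points(ls, "tibia_medial_curve", region_map),
                     region_points(ls, "femur_medial_curve", region_map))
  condyles <- rbind(region_points(ls, "femur_medial_condyle", region_map),
                    region_points(ls, "femur_lateral_condyle", region_map))
  plateaus <- rbind(region_points(ls, "tibia_medial_plateau_anterior", region_map),
                    region_points(ls, "tibia_lateral_plateau_anterior", region_map))

  L1 <- supporting_line(lat_curve, c(1, 0))
  L4 <- supporting_line(med_curve, c(-1, 0))
  L2 <- supporting_line(condyles, c(0, 1))
  L3 <- supporting_line(plateaus, c(0, -1))

  A <- line_intersect(L3, L1)
  B <- line_intersect(L3, L4)
  C <- line_intersect(L2, L1)
  D <- line_intersect(L2, L4)
  if (is.null(A) || is.null(B) || is.null(C) || is.null(D)) {
    stop("framework error: a border line is parallel to a joint line",
         call. = FALSE)
  }
  AB <- vnorm(B - A)
  CD <- vnorm(D - C)
  if (AB <= 0 || CD <= 0) stop("framework error: zero corner distance", call. = FALSE)

  tibial_axis <- new_line(A, B - A, canonicalize = FALSE)
  femoral_axis <- new_line(C, D - C, canonicalize = FALSE)

  # L3 normal pointing toward the femur, L2 normal toward the tibia
  n3 <- rot90ccw(tibial_axis$dir)
  if (sum(n3 * (colMeans(condyles) - A)) < 0) n3 <- -n3
  n2 <- rot90ccw(femoral_axis$dir)
  if (sum(n2 * (colMeans(plateaus) - C)) < 0) n2 <- -n2

  band_pair <- function(S, from_far) {
    outer <- if (from_far) S - (2 / 15) * S else (2 / 15) * S
    step <- (3 / 20) * S
    inner <- if (from_far) outer - step else outer + step
    list(outer = outer, inner = inner)
  }
  bands <- list(
    lateral = list(tibia = band_pair(AB, FALSE), femur = band_pair(CD, FALSE)),
    medial = list(tibia = band_pair(AB, TRUE), femur = band_pair(CD, TRUE))
  )
  # compartment bands must not cross on either joint line
  if (bands$lateral$tibia$inner >= bands$medial$tibia$inner ||
      bands$lateral$femur$inner >= bands$medial$femur$inner) {
    stop("framework error: compartment bands overlap", call. = FALSE)
  }

  structure(
    list(L1 = L1, L2 = L2, L3 = L3, L4 = L4,
         A = A, B = B, C = C, D = D, AB = AB, CD = CD,
         tibial_axis = tibial_axis, femoral_axis = femoral_axis,
         n3_femur = n3, n2_tibia = n2,
         bands = bands,
         corner_convention = "A=lateral tibial, B=medial tibial, C=lateral femoral, D=medial femoral",
         lateral_plateau_range = attr(region_map, "lateral_plateau")),
    class = "knee_framework"
  )
}

#' @export
print.knee_framework <- function(x, ...) {
  cat(sprintf("<knee_framework> AB = %.2f px, CD = %.2f px\n", x$AB, x$CD))
  cat(sprintf("  tibial bands (stations from A): lateral [%.2f, %.2f], medial [%.2f, %.2f]\n",
              x$bands$lateral$tibia$outer, x$bands$lateral$tibia$inner,
              x$bands$medial$tibia$outer, x$bands$medial$tibia$inner))
  invisible(x)
}

#' Serialize a framework to JSON for debugging overlays
#'
#' @param fw a `knee_framework`.
#' @param path optional output path; returns the JSON string when `NULL`.
#' @export
framework_json <- function(fw, path = NULL) {
  obj <- list(
    L1 = list(point = fw$L1$point, dir = fw$L1$dir),
    L2 = list(point = fw$L2$point, dir = fw$L2$dir),
    L3 = list(point = fw$L3$point, dir = fw$L3$dir),
    L4 = list(point = fw$L4$point, dir = fw$L4$dir),
    corners = list(A = fw$A, B = fw$B, C = fw$C, D = fw$D),
    AB = fw$AB, CD = fw$CD, bands = fw$bands,
    corner_convention = fw$corner_convention
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
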