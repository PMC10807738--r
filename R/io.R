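# Image/report I/O and run configuration.

#' Read a grayscale radiograph image
#'
#' Supports 8/16-bit PNG and TIFF. The returned pixel matrix is in
#' MONOCHROME2 convention (higher grey = more attenuation) on a 0-65535
#' scale. Pixel spacing must be supplied (via `pixel_spacing` or the run
#' configuration): joint space widths and eminence heights are millimetre
#' quantities and cannot be reported without it. DICOM files are not read
#' by this build; convert them to 16-bit PNG/TIFF first.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param pixel_spacing pixel spacing in mm/px.
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @return list with `pixels` (numeric matrix), `pixel_spacing`,
#'   `laterality`, `source`.
#' @export
read_image <- function(path, pixel_spacing = NULL, laterality = "unknown") {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcm" || ext == "dicom") {
    stop("DICOM input is not supported by this build; convert to 16-bit PNG or TIFF",
         call. = FALSE)
  }
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    pix <- round(arr * 65535)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    pix <- arr
    if (max(pix) <= 1) pix <- round(pix * 65535)
  } else {
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  }
  if (is.null(pixel_spacing)) {
    stop("pixel spacing unavailable: supply it in the run configuration",
         call. = FALSE)
  }
  if (pixel_spacing <= 0) stop("pixel spacing must be > 0", call. = FALSE)
  list(pixels = pix, pixel_spacing = pixel_spacing,
       laterality = laterality, source = path)
}

#' Write a phantom image as 16-bit TIFF
#'
#' @param image numeric grey matrix on the 0-65535 scale.
#' @param path output path (`.tif`).
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable the measurement pipeline reads, so a report plus
#' its configuration hash fully determines a rerun.
#'
#' @param pixel_spacing pixel spacing in mm/px (required for measurement).
#' @param laterality `"left"`, `"right"` or `"unknown"`.
#' @param lateral_plateau lateral tibial plateau landmark range, `"20_25"`
#'   (default) or `"20_26"`.
#' @param jlca_method `"framework_l3"` (default) or `"landmarks_7_26"`.
#' @param n_per_compartment inscribed circles per compartment (default 15).
#' @param wedge a [wedge_spec()] (required for intensity measurement;
#'   `NULL` skips the intensity stage).
#' @param seed seed for any stochastic option (recorded for audit).
#' @return list of class `run_config` with a `hash` field.
#' @export
run_config <- function(pixel_spacing = NULL,
                       laterality = c("unknown", "left", "right"),
                       lateral_plateau = c("20_25", "20_26"),
                       jlca_method = c("framework_l3", "landmarks_7_26"),
                       n_per_compartment = 15L,
                       wedge = NULL, seed = 1L) {
  laterality <- match.arg(laterality)
  lateral_plateau <- match.arg(lateral_plateau)
  jlca_method <- match.arg(jlca_method)
  cfg <- list(pixel_spacing = pixel_spacing, laterality = laterality,
              lateral_plateau = lateral_plateau, jlca_method = jlca_method,
              n_per_compartment = as.integer(n_per_compartment),
              wedge = if (!is.null(wedge)) unclass(wedge),
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonical JSON serialization
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the full measurement pipeline on one radiograph
#'
#' Executes canonicalization, framework construction, joint space width
#' measurement, wedge calibration plus subchondral intensity measurement
#' (when a wedge spec is configured), JLCA and eminence heights, and
#' assembles a one-row measurement report. Identical inputs and
#' configuration produce bit-identical reports: nothing in the pipeline is
#' stochastic.
#'
#' For left knees the landmarks, the image and the wedge ROI are all
#' mirrored to the canonical right-knee frame before measurement, so the
#' wedge's ascending-thickness convention (thickness growing along +x)
#' holds in the frame where it is sampled.
#'
#' @param image an image list from [read_image()], or a bare pixel matrix.
#' @param landmarks a [landmark_set()] or a landmark file path.
#' @param config a [run_config()].
#' @return a one-row data.frame (class `measurement_report`) with columns
#'   for every measured parameter (units in the column names), quality
#'   flags, the configuration hash and the package version.
#' @export
measure_radiograph <- function(image, landmarks, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  ls <- stage("landmarks", {
    if (is.character(landmarks)) {
      read_landmarks(landmarks, laterality = config$laterality)
    } else landmarks
  })
  if (ls$laterality == "unknown" && config$laterality != "unknown") {
    ls$laterality <- config$laterality
  }
  pix <- if (is.list(image)) image$pixels else image
  spacing <- config$pixel_spacing %||%
    (if (is.list(image)) image$pixel_spacing else NULL)
  if (is.null(spacing)) {
    stop("stage 'config': pixel spacing unavailable", call. = FALSE)
  }
  region_map <- knee_region_map(config$lateral_plateau)

  ls_c <- stage("canonicalize", canonicalize(ls, ncol(pix)))
  pix_c <- if (ls_c$mirrored) pix[, ncol(pix):1, drop = FALSE] else pix
  fw <- stage("framework", build_framework(ls_c, region_map))
  jsw <- stage("jsw", measure_jsw(ls_c, fw, spacing, region_map,
                                  config$n_per_compartment))
  ang <- stage("jlca", jlca(fw, ls_c, config$jlca_method, region_map))
  emi <- stage("eminence", eminence_heights(ls_c, fw, spacing, region_map))

  have_wedge <- !is.null(config$wedge)
  if (have_wedge) {
    roi <- config$wedge$roi
    if (ls_c$mirrored && config$wedge$orientation == "vertical") {
      # wedge thickness ascends along +x in the canonical frame; mirror the
      # ROI together with the image
      roi[1] <- ncol(pix) - roi[1] - roi[3]
    }
    wspec <- wedge_spec(config$wedge$thicknesses_mm, roi,
                        config$wedge$margin, config$wedge$orientation)
    calib <- stage("calibration", {
      regions <- detect_wedge(pix_c, wspec)
      build_calibration(regions, pix_c, wspec)
    })
    intens <- stage("intensities", measure_intensities(pix_c, fw, calib))
    s <- intens$summary
    mm <- function(b, comp) s$mean_mmal[s$bone == b & s$compartment == comp]
  } else {
    intens <- NULL
    mm <- function(b, comp) NA_real_
  }

  flags <- c(
    if (jsw$extrapolated) "extrapolated_boundary",
    if (length(jsw$crossing_stations)) "crossing_circles",
    if (have_wedge && intens$clamped) "calibration_clamped",
    if (ang$flagged) "implausible_jlca",
    if (ls_c$mirrored) "mirrored_left_knee"
  )
  report <- data.frame(
    mean_medial_jsw_mm = jsw$mean_medial_jsw_mm,
    mean_lateral_jsw_mm = jsw$mean_lateral_jsw_mm,
    minimal_jsw_mm = jsw$minimal_jsw_mm,
    minimal_jsw_compartment = jsw$minimal_jsw_compartment,
    n_circles = jsw$n_circles,
    jlca_deg = ang$jlca_deg,
    jlca_abs_deg = ang$jlca_abs_deg,
    jlca_method = ang$method,
    eminence_medial_mm = emi$medial_mm,
    eminence_lateral_mm = emi$lateral_mm,
    eminence_assignment = paste0("medial=", emi$assignment["medial"],
                                 ",lateral=", emi$assignment["lateral"]),
    tibia_medial_mmal = mm("tibia", "medial"),
    tibia_lateral_mmal = mm("tibia", "lateral"),
    femur_medial_mmal = mm("femur", "medial"),
    femur_lateral_mmal = mm("femur", "lateral"),
    flags = paste(flags, collapse = ";"),
    config_hash = config$hash,
    software_version = as.character(utils::packageVersion("kneemorph")),
    stringsAsFactors = FALSE
  )
  class(report) <- c("measurement_report", "data.frame")
  report
}

#' Run the pipeline from files
#'
#' @param image_path radiograph path (PNG/TIFF).
#' @param landmarks_path landmark point-list path.
#' @param config a [run_config()].
#' @return a `measurement_report` (see [measure_radiograph()]) with a
#'   `source` column naming the input files.
#' @export
run_pipeline <- function(image_path, landmarks_path, config) {
  img <- read_image(image_path, pixel_spacing = config$pixel_spacing,
                    laterality = config$laterality)
  rep <- measure_radiograph(img, landmarks_path, config)
  rep$source <- paste(image_path, landmarks_path, sep = "|")
  rep
}

#' Run the pipeline over a batch, recording failures
#'
#' @param files data.frame with columns `image` and `landmarks`.
#' @param config a [run_config()].
#' @param fail_fast stop at the first failure instead of recording it.
#' @return list with `reports` (row-bound measurement reports) and
#'   `failures` (data.frame of file/error pairs).
#' @export
run_batch <- function(files, config, fail_fast = FALSE) {
  reports <- list()
  failures <- list()
  for (i in seq_len(nrow(files))) {
    res <- tryCatch(
      run_pipeline(files$image[i], files$landmarks[i], config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (fail_fast) stop(res)
      failures[[length(failures) + 1]] <- data.frame(
        image = files$image[i], landmarks = files$landmarks[i],
        error = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      reports[[length(reports) + 1]] <- res
    }
  }
  list(
    reports = if (length(reports)) do.call(rbind, reports) else NULL,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(image = character(), landmarks = character(),
                 error = character(), stringsAsFactors = FALSE)
  )
}

#' Write measurement reports to CSV or JSON
#'
#' Column order is deterministic (the report construction order); units are
#' part of the column names.
#'
#' @param reports a `measurement_report` data.frame (one or more rows).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.null(reports) || nrow(reports) < 1) {
    stop("need at least one report", call. = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(reports, path, row.names = FALSE)
  } else {
    jsonlite::write_json(reports, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a report back (JSON round trip)
#'
#' @param path JSON report path.
#' @return data.frame of report rows.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path)
}
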