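#' Define a circular cone-beam scan geometry
#'
#' Distances follow a typical dental CBCT device: 30 cm source-to-isocenter
#' and 55 cm source-to-detector, a flat panel of 2000 x 1000 pixels at
#' 0.2 mm pitch, and 360 projections at 1 degree intervals.  The rotation
#' axis is the volume z-axis through the isocenter; projection k views from
#' angle k * `angular_step` degrees, counterclockwise about +z, with angle 0
#' placing the source on the +x axis.
#'
#' @param source_to_isocenter cm.
#' @param source_to_detector cm; must exceed `source_to_isocenter`.
#' @param detector_cols,detector_rows detector pixel counts (u: in-plane,
#'   v: along the rotation axis).
#' @param detector_pitch detector pixel pitch in mm.
#' @param n_projections number of projections.
#' @param angular_step degrees between projections.
#' @return A `scan_geometry` object.
#' @export
#' @examples
#' scan_geometry(detector_cols = 128, detector_rows = 64,
#'               n_projections = 60, angular_step = 6)
scan_geometry <- function(source_to_isocenter = 30,
                          source_to_detector = 55,
                          detector_cols = 2000, detector_rows = 1000,
                          detector_pitch = 0.2,
                          n_projections = 360, angular_step = 1) {
  if (source_to_isocenter <= 0 ||
      source_to_detector <= source_to_isocenter) {
    stop("need source_to_detector > source_to_isocenter > 0")
  }
  if (detector_cols < 1 || detector_rows < 1 || detector_pitch <= 0) {
    stop("invalid detector specification")
  }
  if (n_projections < 1 || angular_step <= 0) {
    stop("invalid angular sampling")
  }
  structure(list(
    source_to_isocenter = source_to_isocenter,
    source_to_detector = source_to_detector,
    detector_cols = as.integer(detector_cols),
    detector_rows = as.integer(detector_rows),
    detector_pitch = detector_pitch,
    n_projections = as.integer(n_projections),
    angular_step = angular_step
  ), class = "scan_geometry")
}

geometry_angles <- function(geometry) {
  (seq_len(geometry$n_projections) - 1) * geometry$angular_step
}

is_full_scan <- function(geometry) {
  abs(geometry$n_projections * geometry$angular_step - 360) < 1e-6
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry> SID ", x$source_to_isocenter, " cm, SDD ",
      x$source_to_detector, " cm, detector ", x$detector_cols, "x",
      x$detector_rows, " @ ", x$detector_pitch, " mm, ",
      x$n_projections, " views x ", x$angular_step, " deg\n", sep = "")
  invisible(x)
}
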