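# Diameter criterion: mask extents converted to millimetres under the
# optical calibration.

#' Lesion diameter in millimetres
#'
#' Measures the mask bounding-box extents along x (columns) and y (rows),
#' converts the larger one to millimetres using the matching axis's
#' mm-per-pixel ratio, and clamps the result to the criterion range
#' `[0.5, 5]`. Under the default calibration both ratios equal 0.125 mm/px,
#' so either axis choice yields the same conversion.
#'
#' @param mask A [lesion_mask].
#' @param calib A [calibration].
#' @return A list of class `diameter_result` with fields `nr_x`, `nr_y`
#'   (pixel extents), `m_mm` (diameter in mm) and `score_d`.
#' @export
diameter_mm <- function(mask, calib = default_calibration()) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(calib, "calibration"))
  idx <- which(mask$member, arr.ind = TRUE)
  nr_y <- diff(range(idx[, 1])) + 1L
  nr_x <- diff(range(idx[, 2])) + 1L
  m_mm <- if (nr_x >= nr_y) nr_x * calib$mm_per_px_x else nr_y * calib$mm_per_px_y
  structure(list(
    nr_x = nr_x, nr_y = nr_y, m_mm = m_mm,
    score_d = min(5, max(0.5, m_mm))
  ), class = "diameter_result")
}
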