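# Optical calibration: pixel frame vs physical field, used to convert mask
# extents into millimetres.

#' Imaging calibration
#'
#' Maps the pixel frame onto the physical field imaged by the device. The
#' defaults describe a 160 x 120 px frame covering a 20 x 15 mm field at
#' fixed focus, i.e. 0.125 mm per pixel on both axes.
#'
#' @param width_px,height_px Frame resolution in pixels.
#' @param width_mm,height_mm Physical field size in millimetres.
#' @return An object of class `calibration` with derived `mm_per_px_x` and
#'   `mm_per_px_y`. A warning is raised when the two ratios differ by more
#'   than 1% (anisotropic pixels).
#' @export
calibration <- function(width_px = 160, height_px = 120,
                        width_mm = 20, height_mm = 15) {
  vals <- c(width_px, height_px, width_mm, height_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_validation("all calibration fields must be positive numbers")
  }
  rx <- width_mm / width_px
  ry <- height_mm / height_px
  if (abs(rx - ry) / max(rx, ry) > 0.01) {
    warning(sprintf(
      "anisotropic calibration: %.4f mm/px (x) vs %.4f mm/px (y)", rx, ry
    ), call. = FALSE)
  }
  structure(list(width_px = width_px, height_px = height_px,
                 width_mm = width_mm, height_mm = height_mm,
                 mm_per_px_x = rx, mm_per_px_y = ry),
            class = "calibration")
}

#' @rdname calibration
#' @export
default_calibration <- function() calibration()
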