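# Orchestration of the four ABCD criterion computations.

#' Feature-computation configuration
#'
#' Tunable knobs of the ABCD feature stage. Defaults follow the published
#' operating point of the method: a 5%-of-area non-overlap threshold, a
#' border irregularity threshold of 15, and mean aggregation of the six
#' chi-square values.
#'
#' @param delta_a_frac Non-overlap threshold as a fraction of the mole area.
#' @param acolor_bins Histogram bins per channel for colour asymmetry.
#' @param acolor_agg Aggregation of the six chi-square values.
#' @param border_threshold Sector irregularity threshold.
#' @param border_stat Border statistic: radial-distance or boundary-gray
#'   standard deviation.
#' @param color_mode Palette distance mode, see [color_distances()].
#' @param align Whether to centre/rotate onto principal axes first.
#' @return An object of class `abcd_config`.
#' @export
abcd_config <- function(delta_a_frac = 0.05, acolor_bins = 32L,
                        acolor_agg = c("mean", "sum", "max"),
                        border_threshold = 15,
                        border_stat = c("radius", "intensity"),
                        color_mode = c("mean", "perpixel"),
                        align = TRUE) {
  structure(list(
    delta_a_frac = delta_a_frac,
    acolor_bins = as.integer(acolor_bins),
    acolor_agg = match.arg(acolor_agg),
    border_threshold = border_threshold,
    border_stat = match.arg(border_stat),
    color_mode = match.arg(color_mode),
    align = isTRUE(align)
  ), class = "abcd_config")
}

#' Compute the four ABCD criterion scores
#'
#' Runs the full feature chain on a preprocessed colour image and its
#' lesion mask: principal-axis alignment, shape and colour asymmetry (A),
#' eight-sector border irregularity (B), palette colour distances (C) and
#' the calibrated diameter (D). All intermediates are returned alongside
#' the scores.
#'
#' @param img A preprocessed [rgb_image].
#' @param mask The [lesion_mask] from segmentation.
#' @param calib A [calibration].
#' @param palette A [color_palette].
#' @param config An [abcd_config].
#' @return An object of class `abcd_result` with fields `a`, `b`, `c`, `d`
#'   and intermediate lists `asymmetry`, `border`, `color`, `diameter`.
#' @export
compute_abcd <- function(img, mask, calib = default_calibration(),
                         palette = default_palette(),
                         config = abcd_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "lesion_mask"),
            inherits(calib, "calibration"), inherits(palette, "color_palette"),
            inherits(config, "abcd_config"))
  al <- if (config$align) {
    .stage("align", align_principal_axes(img, mask))
  } else {
    list(image = img, mask = mask, angle = 0)
  }

  novl_lr <- .stage("asymmetry", nonoverlap(al$mask, "vertical"))
  novl_ud <- .stage("asymmetry", nonoverlap(al$mask, "horizontal"))
  d_idx <- .stage("asymmetry",
                  delta_a(novl_lr, novl_ud, al$mask$area, config$delta_a_frac))
  acolor <- .stage("asymmetry",
                   color_asymmetry(al$image, al$mask, config$acolor_bins,
                                   config$acolor_agg))
  a <- asymmetry_score(d_idx, acolor)

  gray_al <- if (config$border_stat == "intensity") to_gray(al$image) else NULL
  sec <- .stage("border",
                sector_profiles(al$mask, 8L, config$border_stat, gray_al))
  b <- border_score(sec, config$border_threshold)

  cx <- .stage("color",
               color_distances(al$image, al$mask, palette, config$color_mode))
  t0 <- color_thresholds(palette)
  cscore <- color_score(cx, t0)

  diam <- .stage("diameter", diameter_mm(al$mask, calib))

  structure(list(
    a = a, b = b, c = cscore, d = diam$score_d,
    asymmetry = list(novl_lr = novl_lr, novl_ud = novl_ud,
                     delta_a = d_idx, acolor = acolor),
    border = list(sector_std = sec, threshold = config$border_threshold),
    color = list(cx = cx, t0 = t0),
    diameter = list(nr_x = diam$nr_x, nr_y = diam$nr_y, m_mm = diam$m_mm),
    angle = al$angle
  ), class = "abcd_result")
}

#' @export
print.abcd_result <- function(x, ...) {
  cat("ABCD criterion scores\n")
  cat(sprintf("  A (asymmetry) : %.4f  (delta = %d, acolor = %.5f)\n",
              x$a, x$asymmetry$delta_a, x$asymmetry$acolor))
  cat(sprintf("  B (border)    : %d  (sector std: %s)\n",
              x$b, paste(sprintf("%.2f", x$border$sector_std), collapse = " ")))
  cat(sprintf("  C (colour)    : %d  (matched: %s)\n", x$c,
              paste(names(x$color$cx)[x$color$cx <= x$color$t0],
                    collapse = ", ")))
  cat(sprintf("  D (diameter)  : %.2f  (%.2f mm, extents %d x %d px)\n",
              x$d, x$diameter$m_mm, x$diameter$nr_x, x$diameter$nr_y))
  invisible(x)
}
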