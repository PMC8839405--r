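# Colour criterion: Euclidean distances of the mole's colour against the
# six-colour reference palette.

#' Per-colour palette distances
#'
#' Default mode `"mean"`: for each palette colour, the minimum Euclidean
#' distance between any of its reference shades and the mean normalised RGB
#' of the masked pixels (one representative distance per colour). Mode
#' `"perpixel"`: the minimum over masked pixels and shades of the per-pixel
#' distance (a colour counts as soon as any pixel matches any shade).
#'
#' @param img An [rgb_image].
#' @param mask A [lesion_mask] (at least one pixel).
#' @param palette A [color_palette].
#' @param mode `"mean"` or `"perpixel"`.
#' @return Named numeric vector of distances, one per palette colour.
#' @export
color_distances <- function(img, mask, palette,
                            mode = c("mean", "perpixel")) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "lesion_mask"),
            inherits(palette, "color_palette"))
  mode <- match.arg(mode)
  if (img$height != mask$height || img$width != mask$width) {
    abort_validation("image and mask dimensions differ")
  }
  m <- mask$member
  if (!any(m)) abort_validation("empty mask")
  pix <- cbind(img$pixels[, , 1][m], img$pixels[, , 2][m], img$pixels[, , 3][m])
  if (mode == "mean") {
    mu <- colMeans(pix)
    vapply(palette$shades, function(sh) {
      sqrt(min(rowSums(sweep(sh, 2L, mu)^2)))
    }, numeric(1))
  } else {
    vapply(palette$shades, function(sh) {
      best <- Inf
      for (i in seq_len(nrow(sh))) {
        d2 <- (pix[, 1] - sh[i, 1])^2 + (pix[, 2] - sh[i, 2])^2 +
          (pix[, 3] - sh[i, 3])^2
        best <- min(best, min(d2))
      }
      sqrt(best)
    }, numeric(1))
  }
}

#' Colour criterion score
#'
#' Counts the palette colours whose distance falls at or below their
#' threshold; the count is floored at 1 (every mole has at least one
#' colour).
#'
#' @param cx Numeric vector of 6 per-colour distances.
#' @param t0 Numeric vector of 6 per-colour thresholds.
#' @return Integer colour score C in `[1, 6]`.
#' @export
color_score <- function(cx, t0) {
  if (length(cx) != length(t0)) {
    abort_validation(sprintf(
      "distance/threshold length mismatch: %d vs %d", length(cx), length(t0)
    ))
  }
  if (any(!is.finite(cx)) || any(cx < 0) || any(!is.finite(t0)) || any(t0 <= 0)) {
    abort_validation("distances must be non-negative and thresholds positive")
  }
  max(1L, sum(cx <= t0))
}
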