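# Border criterion: irregularity of the lesion outline over 8 angular
# sectors.

#' Per-sector border irregularity profiles
#'
#' Boundary pixels (mask pixels with at least one non-mask 4-neighbour) are
#' assigned to `n_sectors` equal angular sectors around the centroid;
#' sector 1 starts at angle 0 (east of the centroid) and sectors proceed
#' counter-clockwise. The default statistic is the population standard
#' deviation of the centroid-to-boundary radial distance (in pixels) within
#' each sector; a perfect circle gives values near 0, spiky outlines large
#' values. The alternative `"intensity"` statistic is the standard
#' deviation of the gray level on the boundary pixels of each sector.
#'
#' @param mask A [lesion_mask] with area of at least 16 px.
#' @param n_sectors Number of angular sectors (8 for the B criterion).
#' @param stat `"radius"` (default) or `"intensity"`.
#' @param gray A [gray_image], required for the intensity statistic.
#' @return Numeric vector of `n_sectors` non-negative values; empty sectors
#'   yield 0 with a warning.
#' @export
sector_profiles <- function(mask, n_sectors = 8L,
                            stat = c("radius", "intensity"), gray = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  stat <- match.arg(stat)
  if (mask$area < 16L) {
    abort_validation(sprintf(
      "mask area %d px is too small for border profiling (minimum 16)",
      mask$area
    ))
  }
  if (stat == "intensity") {
    if (is.null(gray) || !inherits(gray, "gray_image")) {
      abort_validation("the intensity statistic needs the gray image")
    }
    if (gray$height != mask$height || gray$width != mask$width) {
      abort_validation("gray image and mask dimensions differ")
    }
  }
  m <- mask$member
  h <- nrow(m); w <- ncol(m)
  P <- matrix(FALSE, h + 2L, w + 2L)
  P[2:(h + 1L), 2:(w + 1L)] <- m
  interior <- P[1:h, 2:(w + 1L)] & P[3:(h + 2L), 2:(w + 1L)] &
    P[2:(h + 1L), 1:w] & P[2:(h + 1L), 3:(w + 2L)]
  boundary <- m & !interior
  idx <- which(boundary, arr.ind = TRUE)
  dy <- mask$centroid[1] - idx[, 1]   # y axis pointing up
  dx <- idx[, 2] - mask$centroid[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  sec <- pmin(n_sectors, floor(ang / (2 * pi / n_sectors)) + 1L)
  vals <- if (stat == "radius") sqrt(dy^2 + dx^2) else gray$values[idx]
  out <- numeric(n_sectors)
  for (s in seq_len(n_sectors)) {
    v <- vals[sec == s]
    if (length(v) == 0L) {
      warning(sprintf("sector %d has no boundary pixels; profile set to 0", s),
              call. = FALSE)
      out[s] <- 0
    } else {
      out[s] <- sqrt(mean((v - mean(v))^2))
    }
  }
  out
}

#' Border criterion score
#'
#' Counts the sectors whose irregularity statistic strictly exceeds the
#' threshold (empirical default 15).
#'
#' @param sector_std Numeric vector of exactly 8 sector statistics.
#' @param threshold Positive irregularity threshold.
#' @return Integer border score B in `[0, 8]`.
#' @export
border_score <- function(sector_std, threshold = 15) {
  if (length(sector_std) != 8L) {
    abort_validation(sprintf(
      "expected 8 sector values, got %d", length(sector_std)
    ))
  }
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0) {
    abort_validation("threshold must be a positive number")
  }
  if (any(!is.finite(sector_std)) || any(sector_std < 0)) {
    abort_validation("sector values must be non-negative")
  }
  sum(sector_std > threshold)
}
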