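# Asymmetry criterion: principal-axis alignment, reflection non-overlap,
# and chi-square colour-histogram distance between opposite lesion halves.

#' Align a lesion to its principal axes
#'
#' Translates the lesion centroid to the raster centre and rotates the
#' frame so that the mask's major principal axis (from second-order central
#' moments) lies horizontal. The image is resampled bilinearly; the mask
#' with nearest-neighbour lookup, re-binarised, and re-cleaned (largest
#' component, holes filled).
#'
#' @param img An [rgb_image].
#' @param mask A [lesion_mask] with area of at least 16 px.
#' @return A list with elements `image`, `mask` and `angle` (the rotation
#'   applied, radians). Degenerate masks (zero second moments) skip the
#'   alignment with a warning and are returned unchanged.
#' @export
align_principal_axes <- function(img, mask) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "lesion_mask"))
  if (mask$area < 16L) {
    abort_validation(sprintf(
      "mask area %d px is too small to align (minimum 16)", mask$area
    ))
  }
  if (img$height != mask$height || img$width != mask$width) {
    abort_validation("image and mask dimensions differ")
  }
  pts <- which(mask$member, arr.ind = TRUE)
  y <- pts[, 1]; x <- pts[, 2]
  cy <- mean(y); cx <- mean(x)
  mxx <- mean((x - cx)^2)
  myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  if (mxx + myy < .Machine$double.eps) {
    warning("degenerate mask: zero second moments, alignment skipped",
            call. = FALSE)
    return(list(image = img, mask = mask, angle = 0))
  }
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  h <- img$height; w <- img$width
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  vx <- matrix(rep(seq_len(w), each = h), h, w) - cx0
  vy <- matrix(rep(seq_len(h), times = w), h, w) - cy0
  # inverse map: rotate output offsets by +theta back into source coords
  xs <- cx + cos(theta) * vx - sin(theta) * vy
  ys <- cy + sin(theta) * vx + cos(theta) * vy

  out <- array(0, c(h, w, 3L))
  xc <- pmin(pmax(xs, 1), w)
  yc <- pmin(pmax(ys, 1), h)
  x0 <- pmin(floor(xc), w - 1L); y0 <- pmin(floor(yc), h - 1L)
  fx <- xc - x0; fy <- yc - y0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  i01 <- cbind(as.vector(y0), as.vector(x0 + 1))
  i10 <- cbind(as.vector(y0 + 1), as.vector(x0))
  i11 <- cbind(as.vector(y0 + 1), as.vector(x0 + 1))
  for (k in 1:3) {
    ch <- img$pixels[, , k]
    v <- (1 - fy) * ((1 - fx) * ch[i00] + fx * ch[i01]) +
      fy * ((1 - fx) * ch[i10] + fx * ch[i11])
    out[, , k] <- matrix(pmin(pmax(v, 0), 1), h, w)
  }

  xr <- round(xs); yr <- round(ys)
  inside <- xr >= 1 & xr <= w & yr >= 1 & yr <= h
  newmem <- matrix(FALSE, h, w)
  newmem[inside] <- mask$member[cbind(yr[inside], xr[inside])]
  if (!any(newmem)) {
    warning("alignment produced an empty mask; returning inputs unchanged",
            call. = FALSE)
    return(list(image = img, mask = mask, angle = 0))
  }
  lab <- .label8(newmem)
  sizes <- tabulate(lab[lab > 0L])
  newmem <- .fill_holes(lab == which.max(sizes))
  new_mask <- lesion_mask(newmem)
  if (abs(new_mask$area - mask$area) / mask$area > 0.02) {
    warning(sprintf(
      "alignment changed the mask area by %.1f%% (from %d to %d px)",
      100 * abs(new_mask$area - mask$area) / mask$area,
      mask$area, new_mask$area
    ), call. = FALSE)
  }
  list(image = rgb_image(out), mask = new_mask, angle = -theta)
}

#' Reflection non-overlap count
#'
#' Number of grid positions where the mask differs from its reflection
#' across the centroid line: a vertical line for the left/right comparison,
#' a horizontal line for the up/down comparison. Perfectly symmetric masks
#' give 0; each unmatched pixel contributes twice (its own site and the
#' empty mirror site).
#'
#' @param mask A [lesion_mask], already centred/aligned.
#' @param axis `"vertical"` (left vs right) or `"horizontal"` (up vs down).
#' @return Non-overlap pixel count.
#' @export
nonoverlap <- function(mask, axis = c("vertical", "horizontal")) {
  stopifnot(inherits(mask, "lesion_mask"))
  axis <- match.arg(axis)
  m <- mask$member
  h <- nrow(m); w <- ncol(m)
  mir <- matrix(FALSE, h, w)
  if (axis == "vertical") {
    m2 <- round(2 * mask$centroid[2])
    src <- m2 - seq_len(w)
    ok <- src >= 1L & src <= w
    mir[, ok] <- m[, src[ok]]
  } else {
    m2 <- round(2 * mask$centroid[1])
    src <- m2 - seq_len(h)
    ok <- src >= 1L & src <= h
    mir[ok, ] <- m[src[ok], ]
  }
  sum(m != mir)
}

#' Shape non-overlap index
#'
#' Grades the two reflection non-overlap counts against a threshold of
#' `frac` (default 5%) of the mole area: 0 when both comparisons fall at or
#' under the threshold, 1 when exactly one does, 2 when neither does.
#'
#' @param novl_lr,novl_ud Non-overlap counts (left/right, up/down).
#' @param area Mole area in pixels.
#' @param frac Threshold fraction of the area.
#' @return Integer 0, 1 or 2.
#' @export
delta_a <- function(novl_lr, novl_ud, area, frac = 0.05) {
  if (any(c(novl_lr, novl_ud) < 0)) {
    abort_validation("non-overlap counts must be non-negative")
  }
  if (length(area) != 1L || area <= 0) {
    abort_validation("area must be positive")
  }
  if (length(frac) != 1L || frac <= 0 || frac >= 1) {
    abort_validation("frac must lie in (0, 1)")
  }
  t0 <- frac * area
  2L - (novl_lr <= t0) - (novl_ud <= t0)
}

#' Chi-square histogram distance
#'
#' `sum((h1 - h2)^2 / (h1 + h2))` over bins with positive mass; bins empty
#' in both histograms are skipped. Inputs are normalised histograms (each
#' sums to 1).
#'
#' @param hist1,hist2 Normalised histograms of equal length.
#' @return Non-negative distance; 0 for identical histograms, at most 2.
#' @export
chi_square <- function(hist1, hist2) {
  if (length(hist1) != length(hist2)) {
    abort_validation(sprintf(
      "histogram length mismatch: %d vs %d", length(hist1), length(hist2)
    ))
  }
  if (any(hist1 < 0) || any(hist2 < 0) ||
      abs(sum(hist1) - 1) > 1e-9 || abs(sum(hist2) - 1) > 1e-9) {
    abort_validation("histograms must be non-negative and sum to 1")
  }
  s <- hist1 + hist2
  keep <- s > 0
  sum((hist1[keep] - hist2[keep])^2 / s[keep])
}

.channel_hist <- function(v, bins) {
  b <- pmin(bins, floor(v * bins) + 1L)
  tabulate(b, nbins = bins) / length(v)
}

#' Colour-distribution asymmetry
#'
#' For each colour channel and each split of the lesion (left vs right of
#' the centroid column, top vs bottom of the centroid row), builds
#' normalised histograms of the masked pixel values and measures their
#' chi-square distance. The six values (3 channels x 2 splits) are
#' aggregated with `agg` (default mean, which keeps the result in `[0, 2]`
#' and commensurate with the shape index).
#'
#' @param img Aligned [rgb_image].
#' @param mask Aligned [lesion_mask].
#' @param bins Histogram bins per channel over `[0, 1]`.
#' @param agg Aggregation over the six chi-square values.
#' @return Non-negative colour-asymmetry value.
#' @export
color_asymmetry <- function(img, mask, bins = 32L,
                            agg = c("mean", "sum", "max")) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "lesion_mask"))
  agg <- match.arg(agg)
  if (bins < 2L) abort_validation("bins must be at least 2")
  m <- mask$member
  h <- nrow(m); w <- ncol(m)
  cc <- mask$centroid[2]; cr <- mask$centroid[1]
  col_m <- matrix(rep(seq_len(w), each = h), h, w)
  row_m <- matrix(rep(seq_len(h), times = w), h, w)
  splits <- list(
    list(a = m & col_m < cc, b = m & col_m > cc),
    list(a = m & row_m < cr, b = m & row_m > cr)
  )
  vals <- numeric(0)
  for (sp in splits) {
    for (k in 1:3) {
      ch <- img$pixels[, , k]
      va <- ch[sp$a]; vb <- ch[sp$b]
      if (length(va) == 0L || length(vb) == 0L) {
        warning("empty lesion half; treating as maximal asymmetry (2.0)",
                call. = FALSE)
        vals <- c(vals, 2)
      } else {
        vals <- c(vals, chi_square(.channel_hist(va, bins),
                                   .channel_hist(vb, bins)))
      }
    }
  }
  switch(agg, mean = mean(vals), sum = sum(vals), max = max(vals))
}

#' Asymmetry criterion score
#'
#' Combines the shape non-overlap index and the colour asymmetry as
#' `(delta + acolor) / 2`, clamped to the criterion range `[0, 2]`.
#'
#' @param d Shape non-overlap index (0, 1 or 2).
#' @param acolor Colour-asymmetry value (non-negative).
#' @return Asymmetry score A in `[0, 2]`.
#' @export
asymmetry_score <- function(d, acolor) {
  if (length(d) != 1L || !d %in% c(0, 1, 2)) {
    abort_validation("d must be 0, 1 or 2")
  }
  if (length(acolor) != 1L || is.na(acolor) || acolor < 0) {
    abort_validation("acolor must be non-negative")
  }
  min(2, max(0, (d + acolor) / 2))
}
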