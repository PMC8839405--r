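# Three-class multilevel Otsu thresholding and extraction of a clean,
# single-component lesion mask.

#' Multi-Otsu thresholds
#'
#' Pair of gray-level thresholds `0 < t1 < t2 <= 255` partitioning the
#' image into the classes `[0, t1)`, `[t1, t2)` and `[t2, 255]` -- lesion
#' edge (darkest), lesion body, and skin.
#'
#' @param t1,t2 Gray-level thresholds.
#' @return An object of class `otsu_thresholds`.
#' @export
otsu_thresholds <- function(t1, t2) {
  if (length(t1) != 1L || length(t2) != 1L || is.na(t1) || is.na(t2) ||
      t1 != round(t1) || t2 != round(t2) ||
      t1 <= 0 || t2 <= t1 || t2 > 255) {
    abort_validation("thresholds must be integers with 0 < t1 < t2 <= 255")
  }
  structure(list(t1 = as.integer(t1), t2 = as.integer(t2)),
            class = "otsu_thresholds")
}

#' Multilevel Otsu thresholding
#'
#' Exhaustively searches the threshold pair maximising the between-class
#' variance of the 256-bin gray histogram over three classes. When several
#' pairs tie (mass-free gray ranges), the lexicographically smallest
#' `(t1, t2)` is returned, which makes the result deterministic across
#' implementations.
#'
#' @param img A [gray_image].
#' @param n_classes Number of classes; only the three-class variant used by
#'   the lesion pipeline is provided.
#' @return An [otsu_thresholds] object.
#' @export
multi_otsu <- function(img, n_classes = 3L) {
  stopifnot(inherits(img, "gray_image"))
  if (n_classes != 3L) {
    abort_validation("multi_otsu supports n_classes = 3 only")
  }
  v <- as.integer(img$values)
  n_levels <- length(unique(v))
  if (n_levels < n_classes) {
    abort_validation(sprintf(
      "image has only %d distinct gray level(s); %d classes need at least %d",
      n_levels, n_classes, n_classes
    ))
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lv <- 0:255
  cp <- c(0, cumsum(p))          # cp[i+1] = P(level <= i - 1)
  cm <- c(0, cumsum(p * lv))
  # between-class variance differs from sum_k S_k^2 / W_k by a constant
  cls <- function(wa, wb) {      # class = levels [wa, wb]
    W <- cp[wb + 2L] - cp[wa + 1L]
    S <- cm[wb + 2L] - cm[wa + 1L]
    out <- ifelse(W > 0, S * S / W, 0)
    out
  }
  best <- -Inf
  best_t <- c(NA_integer_, NA_integer_)
  for (t1 in 1:254) {
    t2 <- (t1 + 1L):255L
    sc <- cls(0L, t1 - 1L) + cls(t1, t2 - 1L) + cls(t2, 255L)
    i <- which.max(sc)
    if (sc[i] > best) {
      best <- sc[i]
      best_t <- c(t1, t2[i])
    }
  }
  otsu_thresholds(best_t[1], best_t[2])
}

# 8-connected labeling by iterative minimum-label propagation: every
# foreground pixel starts with its own linear index and repeatedly adopts
# the smallest label among its 8 neighbours until stable.
.label8 <- function(member) {
  h <- nrow(member); w <- ncol(member)
  L <- matrix(Inf, h, w)
  idx <- which(member)
  if (length(idx) == 0L) return(matrix(0L, h, w))
  L[idx] <- idx
  shift_min <- function(M) {
    P <- matrix(Inf, h + 2L, w + 2L)
    P[2:(h + 1L), 2:(w + 1L)] <- M
    out <- M
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      out <- pmin(out, P[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)])
    }
    out
  }
  repeat {
    Ln <- shift_min(L)
    Ln[!member] <- Inf
    Ln <- pmin(L, Ln)
    if (identical(Ln, L)) break
    L <- Ln
  }
  lab <- matrix(0L, h, w)
  lab[member] <- match(L[member], sort(unique(L[member])))
  lab
}

# fill interior holes: background connectivity is 4-connected (the dual of
# 8-connected foreground); anything not reachable from the border is a hole
.fill_holes <- function(member) {
  h <- nrow(member); w <- ncol(member)
  reach <- matrix(FALSE, h, w)
  bg <- !member
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, w] <- reach[, w] | bg[, w]
  repeat {
    P <- matrix(FALSE, h + 2L, w + 2L)
    P[2:(h + 1L), 2:(w + 1L)] <- reach
    grown <- reach |
      P[1:h, 2:(w + 1L)] | P[3:(h + 2L), 2:(w + 1L)] |
      P[2:(h + 1L), 1:w] | P[2:(h + 1L), 3:(w + 2L)]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  member | (bg & !reach)
}

#' Lesion mask container
#'
#' Binary raster marking mole pixels. After [extract_lesion_mask] the true
#' pixels form a single 8-connected, hole-free component.
#'
#' @param member Logical matrix; `TRUE` marks lesion pixels (at least one).
#' @return An object of class `lesion_mask` with fields `member`, `height`,
#'   `width`, `area` (pixel count) and `centroid` (`c(row, col)`).
#' @export
lesion_mask <- function(member) {
  if (!is.matrix(member) || !is.logical(member)) {
    abort_validation("lesion mask requires a logical matrix")
  }
  area <- sum(member)
  if (area < 1L) {
    abort_validation("lesion mask must contain at least one pixel")
  }
  ind <- which(member, arr.ind = TRUE)
  structure(list(
    member = member, height = nrow(member), width = ncol(member),
    area = area, centroid = c(mean(ind[, 1]), mean(ind[, 2]))
  ), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask %d x %d px, area %d px, centroid (%.1f, %.1f)>\n",
              x$height, x$width, x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Extract the lesion mask
#'
#' Pixels below the upper Otsu threshold (the two darkest classes: lesion
#' edge plus lesion body) form the initial mask; the largest 8-connected
#' component is kept and its interior holes are filled.
#'
#' @param img A [gray_image].
#' @param th An [otsu_thresholds] object for this image.
#' @return A [lesion_mask].
#' @export
extract_lesion_mask <- function(img, th) {
  stopifnot(inherits(img, "gray_image"), inherits(th, "otsu_thresholds"))
  init <- img$values < th$t2
  if (!any(init)) {
    abort_segmentation(sprintf(
      "no lesion found: no pixel below the upper threshold t2 = %d", th$t2
    ))
  }
  lab <- .label8(init)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(sizes)
  lesion_mask(.fill_holes(keep))
}
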