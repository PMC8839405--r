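# Image containers and the preprocessing chain: median denoising,
# grayscale morphological closing (hair removal) and piecewise-linear
# contrast clipping.

#' Colour image container
#'
#' An `rgb_image` is an `height x width x 3` numeric array with all channel
#' values normalised to `[0, 1]`. Images smaller than 8 x 8 pixels are
#' rejected: they cannot carry a measurable lesion.
#'
#' @param pixels Numeric array of dimension `c(height, width, 3)` with
#'   values in `[0, 1]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort_validation("rgb_image requires an array of dimension (height, width, 3)")
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    abort_validation("rgb_image values must be finite")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    abort_validation(sprintf(
      "rgb_image channel values must lie in [0, 1] (found range [%g, %g])",
      rng[1], rng[2]
    ))
  }
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L) {
    abort_validation(sprintf(
      "image too small: %d x %d (minimum is 8 x 8)", d[1], d[2]
    ))
  }
  structure(list(height = d[1], width = d[2], pixels = pixels),
            class = "rgb_image")
}

#' Gray-level image container
#'
#' Holds integer gray levels in `[0, 255]`, the representation used by the
#' histogram-based (Otsu) segmentation.
#'
#' @param values Numeric matrix of whole values in `[0, 255]`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(values) {
  if (!is.matrix(values)) {
    abort_validation("gray_image requires a matrix of gray levels")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort_validation("gray_image values must be finite")
  }
  if (any(values < 0) || any(values > 255) || any(values != round(values))) {
    abort_validation("gray_image values must be whole numbers in [0, 255]")
  }
  structure(list(height = nrow(values), width = ncol(values),
                 values = matrix(as.numeric(values), nrow(values))),
            class = "gray_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px, channels in [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, levels %d..%d>\n",
              x$height, x$width, min(x$values), max(x$values)))
  invisible(x)
}

#' Load a lesion photograph
#'
#' Reads PNG, JPEG, TIFF, PPM/PGM (ASCII or binary) or uncompressed BMP
#' rasters and returns a normalised [rgb_image]. Grayscale files are
#' expanded to three identical channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path Path to the image file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_io(sprintf("cannot read image file '%s'", as.character(path)[1]))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      ppm  = ,
      pgm  = ,
      pnm  = read_pnm(path),
      bmp  = read_bmp(path),
      abort_io(sprintf("unsupported image format '%s' for file '%s'", ext, path))
    ),
    error = function(e) {
      if (inherits(e, "dermabcd_error")) stop(e)
      abort_io(sprintf("failed to decode '%s': %s", path, conditionMessage(e)))
    }
  )
  if (is.matrix(arr)) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (length(dim(arr)) == 3L && dim(arr)[3] == 2L) {
    g <- arr[, , 1L]
    arr <- array(rep(g, 3L), dim = c(dim(g), 3L))
  } else if (length(dim(arr)) == 3L && dim(arr)[3] >= 4L) {
    arr <- arr[, , 1:3, drop = FALSE]
  }
  arr <- pmin(pmax(arr, 0), 1)
  if (dim(arr)[1] < 8L || dim(arr)[2] < 8L) {
    abort_validation(sprintf(
      "image '%s' too small: %d x %d (minimum is 8 x 8)",
      path, dim(arr)[1], dim(arr)[2]
    ))
  }
  rgb_image(arr)
}

# Minimal portable-anymap reader (P2/P3 ASCII, P5/P6 binary), values scaled
# by maxval. Returns a matrix (graymap) or h x w x 3 array (pixmap).
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PNM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
        next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("not a supported PNM file (expected P2/P3/P5/P6)")
  }
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L) {
    stop("corrupt PNM header")
  }
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.double(w) * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else {
    bytes_per <- if (maxval > 255L) 2L else 1L
    raw_vals <- readBin(con, "integer", n = n, size = bytes_per,
                        signed = FALSE, endian = "big")
    as.numeric(raw_vals)
  }
  if (length(vals) < n) stop("truncated PNM pixel data")
  vals <- vals / maxval
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    px <- array(0, c(h, w, 3L))
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    for (k in 1:3) px[, , k] <- matrix(m[, k], nrow = h, ncol = w, byrow = TRUE)
    px
  }
}

# Minimal BMP reader: uncompressed 24/32-bit BITMAPINFOHEADER files.
read_bmp <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM") stop("not a BMP file")
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * c(1, 256, 65536, 16777216))
  offset <- u32(11L)
  w <- u32(19L)
  h_raw <- u32(23L)
  topdown <- h_raw > 2^31 - 1
  h <- if (topdown) 2^32 - h_raw else h_raw
  bpp <- u16(29L)
  compression <- u32(31L)
  if (compression != 0L || !bpp %in% c(24L, 32L)) {
    stop("only uncompressed 24/32-bit BMP files are supported")
  }
  bytes_px <- bpp / 8L
  stride <- ((w * bytes_px + 3L) %/% 4L) * 4L
  px <- array(0, c(h, w, 3L))
  for (row in seq_len(h)) {
    src_row <- if (topdown) row else h - row + 1L
    base <- offset + (src_row - 1L) * stride
    idx <- base + (seq_len(w) - 1L) * bytes_px
    # BMP stores BGR
    px[row, , 1L] <- as.integer(raw[idx + 3L])
    px[row, , 2L] <- as.integer(raw[idx + 2L])
    px[row, , 3L] <- as.integer(raw[idx + 1L])
  }
  px / 255
}

#' Convert a colour image to gray levels
#'
#' Standard luma weighting (0.299 R + 0.587 G + 0.114 B), scaled to
#' `[0, 255]` and rounded to the nearest integer level.
#'
#' @param img An [rgb_image].
#' @param weights Channel weights; must sum to 1.
#' @return A [gray_image].
#' @export
to_gray <- function(img, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(img, "rgb_image"))
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-6) {
    abort_validation("gray conversion weights must be 3 values summing to 1")
  }
  g <- weights[1] * img$pixels[, , 1] + weights[2] * img$pixels[, , 2] +
    weights[3] * img$pixels[, , 3]
  gray_image(round(255 * g))
}

# symmetric reflection padding (edge pixel included in the mirror)
.pad_reflect <- function(m, p) {
  if (p == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  if (p >= h || p >= w) {
    abort_validation("filter radius too large for image size")
  }
  ri <- c(p:1, 1:h, h:(h - p + 1L))
  ci <- c(p:1, 1:w, w:(w - p + 1L))
  m[ri, ci, drop = FALSE]
}

# element-wise median over the (2r+1)^2 square neighbourhood, reflection
# padded; vectorised odd-even transposition sort over the k shifted copies
.median_filter_mat <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  p <- .pad_reflect(m, r)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  k <- nrow(offs)
  vs <- vector("list", k)
  for (i in seq_len(k)) {
    vs[[i]] <- as.vector(p[(1L + r + offs$dy[i]):(h + r + offs$dy[i]),
                           (1L + r + offs$dx[i]):(w + r + offs$dx[i])])
  }
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    j <- start
    while (j < k) {
      a <- vs[[j]]; b <- vs[[j + 1L]]
      vs[[j]] <- pmin(a, b)
      vs[[j + 1L]] <- pmax(a, b)
      j <- j + 2L
    }
  }
  matrix(vs[[(k + 1L) %/% 2L]], h, w)
}

#' Median denoising
#'
#' Replaces every pixel by the median of its `(2 radius + 1)^2`
#' neighbourhood (per channel for colour images). Edges are handled by
#' reflection padding; `radius = 0` is the identity.
#'
#' @param img An [rgb_image] or [gray_image].
#' @param radius Neighbourhood radius in pixels (non-negative integer).
#' @return The filtered image, same type as the input.
#' @export
median_denoise <- function(img, radius = 1L) {
  radius <- .check_radius(radius)
  if (inherits(img, "gray_image")) {
    return(gray_image(.median_filter_mat(img$values, radius)))
  }
  stopifnot(inherits(img, "rgb_image"))
  out <- img$pixels
  for (k in 1:3) out[, , k] <- .median_filter_mat(img$pixels[, , k], radius)
  rgb_image(out)
}

.check_radius <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 0 ||
      radius != round(radius)) {
    abort_validation("radius must be a single non-negative integer")
  }
  as.integer(radius)
}

# disk structuring element offsets for a given radius
.disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

.morph_mat <- function(m, r, fun) {
  h <- nrow(m); w <- ncol(m)
  offs <- .disk_offsets(r)
  out <- NULL
  for (i in seq_len(nrow(offs))) {
    s <- m[(1L + r + offs$dy[i]):(h - r + offs$dy[i]),
           (1L + r + offs$dx[i]):(w - r + offs$dx[i]), drop = FALSE]
    out <- if (is.null(out)) s else fun(out, s)
  }
  out
}

#' Grayscale morphological closing
#'
#' Dilation followed by erosion with a disk structuring element, computed on
#' a reflection-padded copy of the image. Closing raises thin dark
#' structures narrower than the disk (hairs) to the surrounding level and
#' never decreases any pixel.
#'
#' @param img A [gray_image].
#' @param radius Disk radius in pixels; `0` is the identity.
#' @return The closed [gray_image].
#' @export
morphological_close <- function(img, radius = 2L) {
  stopifnot(inherits(img, "gray_image"))
  radius <- .check_radius(radius)
  if (radius == 0L) return(img)
  m <- img$values
  h <- nrow(m); w <- ncol(m)
  # work on a generously padded copy so both passes see reflected context
  p <- .pad_reflect(m, 2L * radius)
  d <- .morph_mat(p, radius, pmax)       # (h + 2r) x (w + 2r)
  e <- .morph_mat(d, radius, pmin)       # h x w
  gray_image(e)
}

#' Piecewise-linear contrast clipping
#'
#' Gray levels at or below `clip_low` map to 0, at or above `clip_high` to
#' 255, and the interval between is stretched linearly. The mapping is
#' monotone non-decreasing.
#'
#' @param img A [gray_image].
#' @param clip_low,clip_high Clip points, `0 <= clip_low < clip_high <= 255`.
#' @return The contrast-enhanced [gray_image].
#' @export
enhance_contrast <- function(img, clip_low, clip_high) {
  stopifnot(inherits(img, "gray_image"))
  if (length(clip_low) != 1L || length(clip_high) != 1L ||
      is.na(clip_low) || is.na(clip_high) ||
      clip_low < 0 || clip_high > 255 || clip_low >= clip_high) {
    abort_validation("clip points must satisfy 0 <= clip_low < clip_high <= 255")
  }
  g <- img$values
  out <- round(255 * (g - clip_low) / (clip_high - clip_low))
  out[g <= clip_low] <- 0
  out[g >= clip_high] <- 255
  gray_image(out)
}

#' Preprocessing parameters
#'
#' @param median_radius Median filter radius in pixels (default 1).
#' @param close_radius Disk radius of the morphological closing (default 2).
#' @param clip_low,clip_high Contrast clip points; `NULL` selects the 0.1
#'   and 99.9 percentiles of the closed gray image automatically.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_radius = 1L, close_radius = 2L,
                              clip_low = NULL, clip_high = NULL) {
  median_radius <- .check_radius(median_radius)
  close_radius <- .check_radius(close_radius)
  if (!is.null(clip_low) && !is.null(clip_high) &&
      (clip_low < 0 || clip_high > 255 || clip_low >= clip_high)) {
    abort_validation("clip points must satisfy 0 <= clip_low < clip_high <= 255")
  }
  structure(list(median_radius = median_radius, close_radius = close_radius,
                 clip_low = clip_low, clip_high = clip_high),
            class = "preprocess_params")
}

#' Preprocess a lesion photograph
#'
#' Applies the chain median filter -> grayscale closing -> contrast
#' clipping. The colour image receives only the median filter (it feeds the
#' colour features); the closing and contrast stretch are applied to the
#' gray conversion, which feeds the segmentation.
#'
#' @param img An [rgb_image].
#' @param params A [preprocess_params] object.
#' @return A list with components `rgb` (denoised [rgb_image]), `gray`
#'   (enhanced [gray_image]) and `clip` (the clip points used).
#' @export
preprocess <- function(img, params = preprocess_params()) {
  stopifnot(inherits(img, "rgb_image"), inherits(params, "preprocess_params"))
  rgb_d <- .stage("median", median_denoise(img, params$median_radius))
  gray <- to_gray(rgb_d)
  gray_c <- .stage("closing", morphological_close(gray, params$close_radius))
  lo <- params$clip_low
  hi <- params$clip_high
  if (is.null(lo) || is.null(hi)) {
    # mild robust stretch: extreme-tail percentiles keep the full
    # edge/body/skin gray structure intact even for small lesions
    q <- stats::quantile(gray_c$values, c(0.001, 0.999), names = FALSE)
    auto_lo <- floor(q[1])
    auto_hi <- ceiling(q[2])
    if (auto_lo >= auto_hi) { auto_lo <- 0; auto_hi <- 255 }
    if (is.null(lo)) lo <- auto_lo
    if (is.null(hi)) hi <- auto_hi
    if (lo >= hi) { lo <- 0; hi <- 255 }
  }
  gray_e <- .stage("contrast", enhance_contrast(gray_c, lo, hi))
  list(rgb = rgb_d, gray = gray_e, clip = c(clip_low = lo, clip_high = hi))
}
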