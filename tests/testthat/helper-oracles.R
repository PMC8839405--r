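# Brute-force oracles and fixture builders, deliberately naive and
# independent of the package's vectorised implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric reflection index (edge pixel duplicated), valid for |overhang| < n
reflect_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

# median filter by direct neighbourhood enumeration
oracle_median <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      vals <- c(vals, m[reflect_idx(i + di, h), reflect_idx(j + dj, w)])
    }
    out[i, j] <- median(vals)
  }
  out
}

# grayscale closing (dilate then erode, disk SE) by direct enumeration on a
# reflected extension of the input
oracle_close <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  se <- list()
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 <= r^2) se[[length(se) + 1L]] <- c(di, dj)
  }
  at <- function(mat, i, j) mat[reflect_idx(i, h), reflect_idx(j, w)]
  dil <- matrix(0, h + 2L * r, w + 2L * r)   # covers i in (1-r)..(h+r)
  for (i in (1L - r):(h + r)) for (j in (1L - r):(w + r)) {
    v <- -Inf
    for (o in se) v <- max(v, at(m, i + o[1], j + o[2]))
    dil[i + r, j + r] <- v
  }
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- Inf
    for (o in se) v <- min(v, dil[i + o[1] + r, j + o[2] + r])
    out[i, j] <- v
  }
  out
}

# exhaustive three-class Otsu: maximise between-class variance
# sum_k W_k (mu_k - mu_T)^2 over all pairs t1 < t2 <= max_level + 1,
# keeping the lexicographically smallest maximiser
oracle_multi_otsu <- function(values) {
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lv <- 0:255
  mu_t <- sum(p * lv)
  top <- max(as.integer(values)) + 1L
  best <- -Inf; best_t <- c(NA, NA)
  for (t1 in 1:(top - 1L)) for (t2 in (t1 + 1L):top) {
    s <- 0
    for (cl in list(0:(t1 - 1L), t1:(t2 - 1L), t2:255L)) {
      wk <- sum(p[cl + 1L])
      if (wk > 0) {
        muk <- sum(p[cl + 1L] * cl) / wk
        s <- s + wk * (muk - mu_t)^2
      }
    }
    if (s > best) { best <- s; best_t <- c(t1, t2) }
  }
  best_t
}

# reflection non-overlap by per-pixel enumeration
oracle_nonoverlap <- function(member, centroid, axis) {
  h <- nrow(member); w <- ncol(member)
  n <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (axis == "vertical") {
      jm <- round(2 * centroid[2]) - j
      mir <- if (jm >= 1 && jm <= w) member[i, jm] else FALSE
    } else {
      im <- round(2 * centroid[1]) - i
      mir <- if (im >= 1 && im <= h) member[im, j] else FALSE
    }
    if (member[i, j] != mir) n <- n + 1L
  }
  n
}

# 8-connected component count by queue-based flood fill
oracle_component_count <- function(member) {
  h <- nrow(member); w <- ncol(member)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (start in which(member)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      i <- (q - 1L) %% h + 1L; j <- (q - 1L) %/% h + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          lin <- (jj - 1L) * h + ii
          if (member[lin] && !seen[lin]) {
            seen[lin] <- TRUE
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  ncomp
}

# TRUE if the mask has interior holes (background not 4-reachable from the
# image border)
oracle_has_holes <- function(member) {
  h <- nrow(member); w <- ncol(member)
  seen <- matrix(FALSE, h, w)
  border <- unique(c(
    which(!member & row(member) %in% c(1L, h)),
    which(!member & col(member) %in% c(1L, w))
  ))
  queue <- border
  seen[border] <- TRUE
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    i <- (q - 1L) %% h + 1L; j <- (q - 1L) %/% h + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        lin <- (jj - 1L) * h + ii
        if (!member[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  any(!member & !seen)
}

# ---- fixture builders -------------------------------------------------

disk_mask <- function(h, w, cy, cx, r) {
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# rasterised ellipse with semi-axes (a, b) rotated by phi (radians, about
# the x axis in row-down coordinates)
ellipse_mask <- function(h, w, cy, cx, a, b, phi = 0) {
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  x <- cols - cx; y <- rows - cy
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# mask orientation from the eigen decomposition of the point covariance,
# normalised to (-pi/2, pi/2] (an orientation is defined modulo pi)
mask_orientation <- function(member) {
  pts <- which(member, arr.ind = TRUE)
  cv <- stats::cov(cbind(pts[, 2], pts[, 1]))
  e <- eigen(cv)
  ori <- atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi
  if (ori > pi / 2) ori - pi else ori
}

# uniform-colour rgb_image over a mask, on a light background
flat_rgb <- function(member, rgb_in = c(0.4, 0.25, 0.2), bg = 0.9) {
  h <- nrow(member); w <- ncol(member)
  px <- array(bg, c(h, w, 3))
  for (k in 1:3) {
    pl <- px[, , k]
    pl[member] <- rgb_in[k]
    px[, , k] <- pl
  }
  rgb_image(px)
}

gray_mat <- function(values) gray_image(values)

# minimal uncompressed 24-bit BMP writer (bottom-up), for reader tests
write_bmp24 <- function(px, path) {
  h <- dim(px)[1]; w <- dim(px)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  data_size <- stride * h
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("BM", con, eos = NULL)
  u32(54 + data_size); u32(0); u32(54)
  u32(40); u32(w); u32(h); u16(1); u16(24); u32(0); u32(data_size)
  u32(2835); u32(2835); u32(0); u32(0)
  for (row in h:1) {
    bytes <- integer(stride)
    for (j in seq_len(w)) {
      base <- (j - 1L) * 3L
      bytes[base + 1L] <- round(px[row, j, 3] * 255)  # B
      bytes[base + 2L] <- round(px[row, j, 2] * 255)  # G
      bytes[base + 3L] <- round(px[row, j, 1] * 255)  # R
    }
    writeBin(as.raw(bytes), con)
  }
  invisible(path)
}
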