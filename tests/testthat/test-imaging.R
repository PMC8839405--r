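# Preprocessing: loading, gray conversion, median filter, closing,
# contrast clipping.

test_that("load_image normalises and expands the supported raster formats", {
  tmp <- withr::local_tempdir()

  # white PNG -> all channels exactly 1
  p_png <- file.path(tmp, "white.png")
  png::writePNG(array(1, c(120, 160, 3)), p_png)
  img <- load_image(p_png)
  expect_s3_class(img, "rgb_image")
  expect_equal(dim(img$pixels), c(120, 160, 3))
  expect_true(all(img$pixels == 1))

  # 8-bit grayscale PGM (binary), value 128 -> ~0.502 on all three channels
  p_pgm <- file.path(tmp, "gray.pgm")
  con <- file(p_pgm, "wb")
  writeChar("P5\n16 10\n255\n", con, eos = NULL)
  writeBin(rep(as.raw(128), 160), con)
  close(con)
  g <- load_image(p_pgm)
  expect_equal(dim(g$pixels), c(10, 16, 3))
  expect_true(all(abs(g$pixels - 128 / 255) < 1e-9))
  expect_equal(g$pixels[1, 1, 1], g$pixels[1, 1, 3])

  # ASCII PPM with distinct channels keeps orientation and channel order
  p_ppm <- file.path(tmp, "tiny.ppm")
  vals <- rep(c(255, 0, 0), 8 * 8)
  writeLines(c("P3", "8 8", "255", paste(vals, collapse = " ")), p_ppm)
  red <- load_image(p_ppm)
  expect_equal(red$pixels[3, 5, ], c(1, 0, 0))

  # BMP round-trip through an independent writer
  px <- array(runif(10 * 12 * 3), c(10, 12, 3))
  px <- round(px * 255) / 255
  p_bmp <- file.path(tmp, "img.bmp")
  write_bmp24(px, p_bmp)
  bmp <- load_image(p_bmp)
  expect_equal(bmp$pixels, px, tolerance = 1e-9)

  # undersized and unreadable inputs
  p_small <- file.path(tmp, "small.png")
  png::writePNG(array(0.5, c(4, 4, 3)), p_small)
  expect_error(load_image(p_small), class = "dermabcd_validation_error")
  expect_error(load_image(file.path(tmp, "nope.png")),
               class = "dermabcd_io_error")
  p_bad <- file.path(tmp, "corrupt.png")
  writeLines("not a png", p_bad)
  expect_error(load_image(p_bad), class = "dermabcd_io_error")
})

test_that("to_gray applies the standard luma weighting", {
  white <- rgb_image(array(1, c(8, 8, 3)))
  black <- rgb_image(array(0, c(8, 8, 3)))
  expect_true(all(to_gray(white)$values == 255))
  expect_true(all(to_gray(black)$values == 0))

  px <- array(0, c(8, 8, 3))
  px[, , 1] <- 1  # pure red
  expect_true(all(to_gray(rgb_image(px))$values == round(0.299 * 255)))
})

test_that("median filter matches the brute-force oracle and its identities", {
  # constant image unchanged, radius 0 is the identity
  const <- gray_image(matrix(77, 9, 9))
  expect_equal(median_denoise(const, 2)$values, const$values)
  rand <- gray_image(matrix(sample(0:255, 81, TRUE), 9, 9))
  expect_equal(median_denoise(rand, 0)$values, rand$values)

  # single bright pixel in a dark field is removed
  spot <- matrix(10, 9, 9); spot[5, 5] <- 250
  expect_true(all(median_denoise(gray_image(spot), 1)$values == 10))

  # brute-force neighbourhood-sort oracle on random fixtures
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(sample(0:255, 81, TRUE), 9, 9)
    expect_equal(median_denoise(gray_image(m), 1)$values,
                     oracle_median(m, 1))
  }
  for (seed in 1:10) {
    set.seed(1000 + seed)
    m <- matrix(sample(0:255, 81, TRUE), 9, 9)
    expect_equal(median_denoise(gray_image(m), 2)$values,
                     oracle_median(m, 2))
  }

  # colour images are filtered channel-wise
  set.seed(3)
  px <- array(sample(0:255, 8 * 8 * 3, TRUE) / 255, c(8, 8, 3))
  got <- median_denoise(rgb_image(px), 1)
  for (k in 1:3) {
    expect_equal(got$pixels[, , k], oracle_median(px[, , k], 1))
  }

  expect_error(median_denoise(const, -1), class = "dermabcd_validation_error")
})

test_that("closing removes thin dark lines, never darkens, and is idempotent", {
  const <- gray_image(matrix(120, 15, 15))
  expect_equal(morphological_close(const, 2)$values, const$values)

  # 1-px dark line across a bright field: raised to background by radius 2
  line <- matrix(200, 15, 15); line[8, ] <- 20
  closed <- morphological_close(gray_image(line), 2)
  expect_true(all(closed$values == 200))
  expect_equal(closed$values, oracle_close(line, 2))

  # closing is extensive and idempotent
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(sample(0:255, 225, TRUE), 15, 15)
    c1 <- morphological_close(gray_image(m), 2)
    expect_true(all(c1$values >= m))
    expect_equal(c1$values, oracle_close(m, 2))
  }
  blob <- matrix(200, 15, 15); blob[6:10, 6:10] <- 30
  c1 <- morphological_close(gray_image(blob), 2)
  expect_equal(morphological_close(c1, 2)$values, c1$values)

  expect_error(morphological_close(const, -2),
               class = "dermabcd_validation_error")
})

test_that("contrast clipping is the stated piecewise-linear map", {
  g <- gray_image(matrix(0:255, 16, 16))
  expect_equal(enhance_contrast(g, 0, 255)$values, g$values)

  ex <- enhance_contrast(gray_image(matrix(c(50, 125, 200, 255), 2, 2)), 50, 200)
  expect_equal(as.vector(ex$values), c(0, round(255 * 75 / 150), 255, 255))
  expect_equal(ex$values[2, 1], 128)

  # monotone non-decreasing on sorted levels
  set.seed(11)
  v <- sort(sample(0:255, 64, TRUE))
  out <- enhance_contrast(gray_image(matrix(v, 8, 8)), 40, 210)$values
  expect_true(all(diff(as.vector(out)[order(v)]) >= 0))

  expect_error(enhance_contrast(g, 200, 100), class = "dermabcd_validation_error")
  expect_error(enhance_contrast(g, 100, 100), class = "dermabcd_validation_error")
})

test_that("preprocess preserves shape and is the identity for neutral params", {
  set.seed(4)
  px <- array(sample(0:255, 20 * 24 * 3, TRUE) / 255, c(20, 24, 3))
  img <- rgb_image(px)
  neutral <- preprocess_params(0, 0, 0, 255)
  out <- preprocess(img, neutral)
  expect_equal(out$rgb$pixels, px)
  expect_equal(out$gray$values, to_gray(img)$values)

  out2 <- preprocess(img, preprocess_params(1, 2, NULL, NULL))
  expect_equal(c(out2$rgb$height, out2$rgb$width), c(20, 24))
  expect_equal(c(out2$gray$height, out2$gray$width), c(20, 24))
  expect_true(out2$clip["clip_low"] < out2$clip["clip_high"])
})
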