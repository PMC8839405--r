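# ABCD feature computations: alignment, asymmetry, border, colour,
# diameter, and their orchestration.

test_that("principal-axis alignment brings a rotated ellipse horizontal", {
  # axis-aligned centered ellipse: alignment is (near) a fixed point
  m0 <- ellipse_mask(120, 160, 60.5, 80.5, 40, 20)
  img0 <- flat_rgb(m0)
  al0 <- align_principal_axes(img0, lesion_mask(m0))
  expect_lt(abs(mask_orientation(al0$mask$member)), pi / 180)
  expect_lt(abs(al0$mask$area - sum(m0)) / sum(m0), 0.02)

  # the same ellipse rotated 30 degrees: recovered orientation within 1 degree
  m30 <- ellipse_mask(120, 160, 60.5, 80.5, 40, 20, phi = 30 * pi / 180)
  al30 <- align_principal_axes(flat_rgb(m30), lesion_mask(m30))
  expect_lt(abs(mask_orientation(al30$mask$member)), pi / 180)
  expect_lt(abs(al30$mask$area - sum(m30)) / sum(m30), 0.02)

  # centroid lands on the raster centre
  expect_equal(al30$mask$centroid, c(60.5, 80.5), tolerance = 0.02)

  # a disk is rotation-invariant: area preserved regardless of angle
  md <- disk_mask(120, 160, 50, 70, 18)
  ald <- align_principal_axes(flat_rgb(md), lesion_mask(md))
  expect_lt(abs(ald$mask$area - sum(md)) / sum(md), 0.02)

  # degenerate and undersized masks
  tiny <- matrix(FALSE, 20, 20); tiny[10, 10] <- TRUE
  expect_error(align_principal_axes(flat_rgb(tiny), lesion_mask(tiny)),
               class = "dermabcd_validation_error")
})

test_that("nonoverlap counts XOR pixels against the centroid reflection", {
  # rectangle centred on the reflection lines: 0 for both axes
  rect <- matrix(FALSE, 21, 31)
  rect[6:16, 6:26] <- TRUE
  mk <- lesion_mask(rect)
  expect_equal(nonoverlap(mk, "vertical"), 0L)
  expect_equal(nonoverlap(mk, "horizontal"), 0L)

  # symmetric mask plus one extra pixel: the pixel and its unmatched
  # mirror site -> 2 (centroid shift is negligible at this scale)
  big <- matrix(FALSE, 41, 61)
  big[11:31, 16:46] <- TRUE
  big[21, 10] <- TRUE
  expect_equal(nonoverlap(lesion_mask(big), "vertical"), 2L)

  # equals the per-pixel enumeration oracle on random masks, and is
  # invariant under mirroring
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(runif(12 * 12) < 0.4, 12, 12)
    if (!any(m)) m[5, 5] <- TRUE
    mk <- lesion_mask(m)
    for (ax in c("vertical", "horizontal")) {
      expect_identical(nonoverlap(mk, ax),
                       oracle_nonoverlap(m, mk$centroid, ax))
    }
    mirrored <- lesion_mask(m[, ncol(m):1])
    expect_identical(nonoverlap(mk, "vertical"),
                     nonoverlap(mirrored, "vertical"))
  }
})

test_that("delta_a grades the two non-overlap counts against 5% of area", {
  expect_equal(delta_a(30, 40, 1000), 0L)
  expect_equal(delta_a(30, 60, 1000), 1L)
  expect_equal(delta_a(60, 30, 1000), 1L)
  expect_equal(delta_a(60, 70, 1000), 2L)
  # the printed counts 1925 and 2340 exceed any in-frame threshold
  expect_equal(delta_a(1925, 2340, 160 * 120), 2L)
  # boundary: exactly at threshold counts as overlap
  expect_equal(delta_a(50, 50, 1000), 0L)
  expect_error(delta_a(-1, 10, 100), class = "dermabcd_validation_error")
  expect_error(delta_a(1, 1, 0), class = "dermabcd_validation_error")
})

test_that("chi_square follows its closed form", {
  expect_equal(chi_square(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(chi_square(c(1, 0), c(0, 1)), 2)
  expect_equal(chi_square(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               0.0625 / 0.75 + 0.0625 / 0.75 + 0.25 / 0.5)
  # zero-sum bins are skipped
  expect_equal(chi_square(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 0)
  expect_error(chi_square(c(1, 0), c(0.2, 0.3, 0.5)),
               class = "dermabcd_validation_error")
  expect_error(chi_square(c(0.6, 0.6), c(0.5, 0.5)),
               class = "dermabcd_validation_error")
})

test_that("color_asymmetry detects half-and-half colouring and nothing else", {
  m <- matrix(FALSE, 40, 60)
  m[11:30, 16:45] <- TRUE

  # uniform colour -> identical histograms on every split
  expect_equal(color_asymmetry(flat_rgb(m), lesion_mask(m)), 0)

  # left half one colour, right half another (different bins in all three
  # channels): L/R chi-square 2 per channel, U/D 0, mean over six = 1
  px <- array(0.9, c(40, 60, 3))
  c1 <- c(0.1, 0.2, 0.3); c2 <- c(0.6, 0.7, 0.8)
  mk <- lesion_mask(m)
  for (k in 1:3) {
    pl <- px[, , k]
    left <- m & col(m) < mk$centroid[2]
    right <- m & col(m) > mk$centroid[2]
    pl[left] <- c1[k]; pl[right] <- c2[k]
    px[, , k] <- pl
  }
  expect_equal(color_asymmetry(rgb_image(px), mk), 1)
  expect_equal(color_asymmetry(rgb_image(px), mk, agg = "sum"), 6)
  expect_equal(color_asymmetry(rgb_image(px), mk, agg = "max"), 2)

  # invariant under swapping the halves
  swapped <- rgb_image(px[, ncol(m):1, ])
  expect_equal(color_asymmetry(swapped, lesion_mask(m[, ncol(m):1])), 1)
})

test_that("asymmetry_score averages and clamps", {
  expect_equal(asymmetry_score(0, 0), 0)
  expect_equal(asymmetry_score(2, 0.0262594), 1.0131297)
  expect_equal(asymmetry_score(2, 5), 2)  # clamped to the criterion range
  # linearity before clamping
  for (a in c(0.1, 0.5, 1.2)) {
    expect_equal(asymmetry_score(1, a) - asymmetry_score(1, 0), a / 2)
  }
  expect_error(asymmetry_score(3, 0), class = "dermabcd_validation_error")
  expect_error(asymmetry_score(1, -0.1), class = "dermabcd_validation_error")
})

test_that("sector profiles measure radial spread per 45-degree sector", {
  # near-circle: only rasterisation noise
  circ <- disk_mask(100, 100, 50.5, 50.5, 30)
  s_circ <- sector_profiles(lesion_mask(circ))
  expect_length(s_circ, 8)
  expect_true(all(s_circ <= 1))

  # ellipse a=40 b=20: every sector spreads more than the circle's, but
  # less than a - b
  ell <- ellipse_mask(120, 160, 60.5, 80.5, 40, 20)
  s_ell <- sector_profiles(lesion_mask(ell))
  expect_true(all(s_ell > s_circ))
  expect_true(all(s_ell < 20))

  # radial spikes in one sector dominate the others by > 5x
  h <- 200; w <- 200
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  dy <- 100.5 - rows; dx <- cols - 100.5
  ang <- atan2(dy, dx) %% (2 * pi)
  rad <- sqrt(dy^2 + dx^2)
  spike <- 20 * sin(16 * ang) * (ang < pi / 4)   # sector 1 only
  star <- rad <= 60 + spike
  s_star <- sector_profiles(lesion_mask(star))
  expect_gt(s_star[1], 5 * max(s_star[-1]))

  expect_error(sector_profiles(lesion_mask(disk_mask(20, 20, 10, 10, 1.5))),
               class = "dermabcd_validation_error")
})

test_that("border_score counts sectors strictly above the threshold", {
  printed <- c(5.8472, 6.5147, 6.06682, 6.4209, 3.31381, 1.5999,
               7.8649, 13.8412)
  expect_equal(border_score(printed), 0L)
  expect_equal(border_score(rep(16, 8)), 8L)
  expect_equal(border_score(c(rep(15, 8))), 0L)      # "exceeds" is strict
  expect_equal(border_score(c(15.0001, rep(1, 7))), 1L)
  # monotone non-decreasing in every sector value
  base <- c(4, 8, 12, 14, 15, 16, 20, 3)
  for (i in 1:8) {
    bumped <- base; bumped[i] <- bumped[i] + 10
    expect_gte(border_score(bumped), border_score(base))
  }
  expect_error(border_score(1:7), class = "dermabcd_validation_error")
})

test_that("colour thresholds follow the first-to-last-shade rule with printed overrides", {
  # agreement with the published thresholds at their printed precision
  t0 <- color_thresholds(default_palette())
  expect_lt(abs(t0[["white"]] - 0.339655), 1e-6)
  expect_lt(abs(t0[["black"]] - 0.339655), 1e-6)
  expect_lt(abs(t0[["light_brown"]] - 0.588233), 1e-6)
  expect_lt(abs(t0[["dark_brown"]] - 0.679252), 1e-6)
  expect_equal(t0[["red"]], 0.818156)
  expect_equal(t0[["bluish_gray"]], 0.415973)

  # without overrides the rule itself is exposed
  pal <- default_palette()
  plain <- color_palette(pal$shades)
  t0p <- color_thresholds(plain)
  expect_equal(unname(t0p["white"]), sqrt(3) * (1 - 0.8039))
})

test_that("color_distances matches closed forms in both modes", {
  pal <- default_palette()
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  mk <- lesion_mask(m)

  # lesion equal to a palette shade everywhere -> that colour's distance 0
  shade <- pal$shades$dark_brown[1, ]
  img <- flat_rgb(m, rgb_in = shade)
  cx <- color_distances(img, mk, pal)
  expect_equal(unname(cx["dark_brown"]), 0)
  expect_equal(color_distances(img, mk, pal, "perpixel"), cx)

  # all-black lesion: distance to white is the distance to its darkest
  # reference shade
  black <- flat_rgb(m, rgb_in = c(0, 0, 0))
  cxb <- color_distances(black, mk, pal)
  expect_equal(unname(cxb["white"]), sqrt(3) * 0.8039, tolerance = 1e-9)
  expect_equal(unname(cxb["black"]), 0)

  # per-pixel mode picks up a minority colour that the mean misses
  px <- img$pixels
  pl <- px[, , 1]; pl[6, 6:8] <- 0; px[, , 1] <- pl
  pl <- px[, , 2]; pl[6, 6:8] <- 0; px[, , 2] <- pl
  pl <- px[, , 3]; pl[6, 6:8] <- 0; px[, , 3] <- pl
  mixed <- rgb_image(px)
  expect_equal(unname(color_distances(mixed, mk, pal, "perpixel")["black"]), 0)
  expect_gt(unname(color_distances(mixed, mk, pal, "mean")["black"]), 0)

  expect_error(color_distances(img, mk, pal, "nope"))
})

test_that("color_score counts matches with a floor of one", {
  cx <- c(1.165395, 0.438254, 0.376436, 0.344173, 0.285576, 0.626262)
  t0 <- c(0.339655, 0.339655, 0.818156, 0.588233, 0.679252, 0.415973)
  expect_equal(color_score(cx, t0), 3L)
  expect_equal(color_score(rep(0, 6), t0), 6L)
  expect_equal(color_score(t0 + 0.01, t0), 1L)   # floor
  expect_equal(color_score(t0, t0), 6L)          # ties count ("<=")
  # monotone non-increasing in each distance
  for (i in 1:6) {
    bumped <- cx; bumped[i] <- bumped[i] + 1
    expect_lte(color_score(bumped, t0), color_score(cx, t0))
  }
  expect_error(color_score(cx[1:5], t0), class = "dermabcd_validation_error")
})

test_that("diameter_mm converts the larger extent with the matching axis ratio", {
  m <- matrix(FALSE, 120, 160)
  m[41:80, 57:104] <- TRUE   # nr_y = 40, nr_x = 48
  dd <- diameter_mm(lesion_mask(m), default_calibration())
  expect_equal(dd$nr_x, 48L)
  expect_equal(dd$nr_y, 40L)
  expect_equal(dd$m_mm, 6)
  expect_equal(dd$score_d, 5)          # clamped at 5

  # square extent: both axes give the same answer under the default ratios
  sq <- matrix(FALSE, 120, 160); sq[41:80, 61:100] <- TRUE
  expect_equal(diameter_mm(lesion_mask(sq))$m_mm, 5)

  # clamping at the low end
  dot <- matrix(FALSE, 120, 160); dot[60:61, 80:81] <- TRUE
  expect_equal(diameter_mm(lesion_mask(dot))$score_d, 0.5)

  # linear in the physical field size at fixed resolution
  m2 <- lesion_mask(m)
  d1 <- diameter_mm(m2, calibration(160, 120, 20, 15))$m_mm
  d2 <- diameter_mm(m2, calibration(160, 120, 40, 30))$m_mm
  expect_equal(d2, 2 * d1)
})

test_that("compute_abcd composes the stages and stays in the score ranges", {
  # symmetric uniform disk: A ~ 0, B = 0, C >= 1, D = diameter * 0.125
  m <- disk_mask(120, 160, 60.5, 80.5, 16)
  img <- flat_rgb(m, rgb_in = default_palette()$shades$dark_brown[1, ])
  res <- compute_abcd(img, lesion_mask(m))
  expect_equal(res$asymmetry$delta_a, 0L)
  expect_lt(res$a, 0.05)
  expect_equal(res$b, 0L)
  expect_gte(res$c, 1L)
  expect_lt(abs(res$diameter$m_mm - 32 * 0.125), 0.26)
  expect_equal(res$d, res$diameter$m_mm)

  # deterministic
  res2 <- compute_abcd(img, lesion_mask(m))
  expect_identical(res, res2)

  # ranges on generated lesions
  for (seed in c(2, 9)) {
    les <- generate_lesion(lesion_spec(
      seed = seed, diameter_mm = 5 + seed %% 3, eccentricity = 0.3,
      boundary_noise_amp = 3, asymmetry_bias = 0.3,
      colors = c(dark_brown = 0.6, light_brown = 0.4),
      hair_count = 2, noise_sigma = 5
    ))
    r <- compute_abcd(les$image, les$mask)
    expect_true(r$a >= 0 && r$a <= 2)
    expect_true(r$b %in% 0:8)
    expect_true(r$c %in% 1:6)
    expect_true(r$d >= 0.5 && r$d <= 5)
  }
})
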