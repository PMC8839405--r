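# Seeded synthetic-lesion generator with analytic ground truth: a
# star-shaped blob (truncated Fourier boundary) on a skin-tone background,
# painted with reference palette shades, with optional hair-like artefacts
# and additive Gaussian noise.

# representative shade row painted for each palette colour (row 1 of light
# brown duplicates row 1 of red, so light brown paints its second shade)
.REP_SHADE <- c(white = 1L, black = 1L, red = 3L, light_brown = 2L,
                dark_brown = 1L, bluish_gray = 1L)

# run expr under a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic lesion specification
#'
#' Describes one synthetic test lesion: its physical size, elliptical
#' elongation, boundary irregularity, left/right mass bias, the palette
#' colours painted into it, and the imaging artefacts (hairs, noise). All
#' randomness in the rendered image flows from `seed`; the ground-truth
#' mask is fully deterministic given the geometric fields, so two specs
#' differing only in `seed` share the same mask.
#'
#' @param seed Integer RNG seed for background texture, hairs and noise.
#' @param diameter_mm Major-axis diameter of the lesion in mm; must fit the
#'   calibrated field.
#' @param eccentricity Elliptical eccentricity in `[0, 1)`; 0 is a circle.
#' @param boundary_noise_amp Amplitude (px) of the sinusoidal boundary
#'   perturbation.
#' @param boundary_waves Angular frequency of the boundary perturbation.
#' @param asymmetry_bias In `[0, 1]`: inflates the lesion radius on the
#'   left side by up to this fraction, creating left/right shape asymmetry.
#' @param colors Named weights over palette colours painted into the
#'   lesion; weights are normalised to sum 1.
#' @param layout How multiple colours are arranged: angular wedges,
#'   left/right halves, or concentric rings.
#' @param hair_count Number of dark 1-px hair-like lines.
#' @param noise_sigma Additive Gaussian pixel noise, in gray levels.
#' @param calibration A [calibration] defining the frame and field.
#' @param rim_width_px,rim_factor Width and darkening factor of the lesion
#'   rim (the darkest "edge" class seen by the three-class segmentation).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(seed = 1L, diameter_mm = 4, eccentricity = 0,
                        boundary_noise_amp = 0, boundary_waves = 7L,
                        asymmetry_bias = 0,
                        colors = c(dark_brown = 1),
                        layout = c("wedge", "halves", "rings"),
                        hair_count = 0L, noise_sigma = 0,
                        calibration = default_calibration(),
                        rim_width_px = 4, rim_factor = 0.55) {
  layout <- match.arg(layout)
  stopifnot(inherits(calibration, "calibration"))
  if (length(seed) != 1L || seed != round(seed)) {
    abort_validation("seed must be a single integer")
  }
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    abort_validation("diameter_mm must be positive")
  }
  if (diameter_mm > min(calibration$width_mm, calibration$height_mm)) {
    abort_validation(sprintf(
      "lesion diameter %.1f mm larger than the %.0f x %.0f mm field",
      diameter_mm, calibration$width_mm, calibration$height_mm
    ))
  }
  if (eccentricity < 0 || eccentricity >= 1) {
    abort_validation("eccentricity must lie in [0, 1)")
  }
  if (asymmetry_bias < 0 || asymmetry_bias > 1) {
    abort_validation("asymmetry_bias must lie in [0, 1]")
  }
  if (is.null(names(colors)) || !all(names(colors) %in% names(.REP_SHADE))) {
    abort_validation(paste0(
      "colors must be named weights over: ",
      paste(names(.REP_SHADE), collapse = ", ")
    ))
  }
  if (any(colors <= 0)) abort_validation("colour weights must be positive")
  colors <- colors / sum(colors)
  if (hair_count < 0 || hair_count != round(hair_count)) {
    abort_validation("hair_count must be a non-negative integer")
  }
  if (noise_sigma < 0) abort_validation("noise_sigma must be non-negative")
  structure(list(
    seed = as.integer(seed), diameter_mm = diameter_mm,
    eccentricity = eccentricity, boundary_noise_amp = boundary_noise_amp,
    boundary_waves = as.integer(boundary_waves),
    asymmetry_bias = asymmetry_bias, colors = colors, layout = layout,
    hair_count = as.integer(hair_count), noise_sigma = noise_sigma,
    calibration = calibration, rim_width_px = rim_width_px,
    rim_factor = rim_factor
  ), class = "lesion_spec")
}

#' Generate a synthetic lesion image with ground truth
#'
#' Renders the lesion described by `spec` onto a light skin-tone background
#' (mean gray level about 210, matching LED-lit, ambient-light-free
#' imaging), then adds hair-like lines and Gaussian noise. Returns the
#' exact rasterised mask and an expected-feature record.
#'
#' @param spec A [lesion_spec].
#' @param palette The [color_palette] whose shades are painted.
#' @return A list of class `synthetic_lesion` with elements `image` (noisy
#'   [rgb_image]), `clean` (noise- and hair-free render), `mask`
#'   (ground-truth [lesion_mask]), `spec`, and `expected` (diameter in mm,
#'   analytic blob area, per-mode expected colour counts).
#' @export
generate_lesion <- function(spec, palette = default_palette()) {
  stopifnot(inherits(spec, "lesion_spec"))
  calib <- spec$calibration
  h <- as.integer(round(calib$height_px))
  w <- as.integer(round(calib$width_px))
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  rx <- calib$mm_per_px_x

  row_m <- matrix(rep(seq_len(h), times = w), h, w)
  col_m <- matrix(rep(seq_len(w), each = h), h, w)
  dy <- cy - row_m
  dx <- col_m - cx
  ang <- atan2(dy, dx) %% (2 * pi)
  rad <- sqrt(dy^2 + dx^2)

  a_px <- spec$diameter_mm / 2 / rx
  b_px <- a_px * sqrt(1 - spec$eccentricity^2)
  # egg-shaped asymmetry: the left half uses an inflated horizontal
  # semi-axis (a displaced circle would stay reflection-symmetric)
  radial <- function(th) {
    ae <- a_px * (1 + spec$asymmetry_bias * (cos(th) < 0))
    r <- ae * b_px / sqrt((b_px * cos(th))^2 + (ae * sin(th))^2)
    pmax(r + spec$boundary_noise_amp *
           sin(spec$boundary_waves * th + 0.7), 1)
  }
  r_fun <- radial(ang)
  member <- rad <= r_fun
  mask <- lesion_mask(.fill_holes(member))

  # colour region assignment
  k <- length(spec$colors)
  cum_w <- cumsum(spec$colors)
  region <- switch(spec$layout,
    wedge = {
      fr <- ang / (2 * pi)
      pmin(k, findInterval(fr, c(0, cum_w), rightmost.closed = TRUE))
    },
    halves = {
      if (k == 1L) matrix(1L, h, w) else ifelse(dx < 0, 1L, pmin(k, 2L))
    },
    rings = {
      fr <- pmin(rad / r_fun, 1)
      pmin(k, findInterval(fr, c(0, cum_w), rightmost.closed = TRUE))
    }
  )

  lesion_rgb <- vapply(names(spec$colors), function(nm) {
    palette$shades[[nm]][.REP_SHADE[[nm]], ]
  }, numeric(3))                      # 3 x k

  rim <- member & rad > (r_fun - spec$rim_width_px)

  out <- .with_seed(spec$seed, {
    bg_tex <- matrix(stats::rnorm(h * w, 0, 2 / 255), h, w)
    base <- array(0, c(h, w, 3L))
    bg_rgb <- c(0.92, 0.80, 0.70)
    for (ch in 1:3) {
      plane <- bg_rgb[ch] + bg_tex
      col_plane <- matrix(lesion_rgb[ch, region], h, w)
      plane[member] <- col_plane[member]
      plane[rim] <- plane[rim] * spec$rim_factor
      base[, , ch] <- plane
    }
    clean <- pmin(pmax(base, 0), 1)

    noisy <- clean
    hair_rgb <- c(0.22, 0.15, 0.10)
    for (i in seq_len(spec$hair_count)) {
      x0 <- stats::runif(1, 1, w)
      y0 <- stats::runif(1, 1, h)
      th <- stats::runif(1, 0, pi)
      tt <- seq(-(w + h), w + h, by = 1)
      px <- round(x0 + tt * cos(th))
      py <- round(y0 + tt * sin(th))
      okp <- px >= 1 & px <= w & py >= 1 & py <= h
      ij <- unique(cbind(py[okp], px[okp]))
      for (ch in 1:3) {
        plane <- noisy[, , ch]
        plane[ij] <- hair_rgb[ch]
        noisy[, , ch] <- plane
      }
    }
    if (spec$noise_sigma > 0) {
      noisy <- noisy + stats::rnorm(length(noisy), 0, spec$noise_sigma / 255)
    }
    list(clean = clean, noisy = pmin(pmax(noisy, 0), 1))
  })

  clean_img <- rgb_image(out$clean)
  t0 <- color_thresholds(palette)
  expected_counts <- vapply(c("mean", "perpixel"), function(md) {
    color_score(color_distances(clean_img, mask, palette, md), t0)
  }, integer(1))

  # analytic blob area: 1/2 integral of r(theta)^2 dtheta
  th_g <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  area_analytic <- sum(radial(th_g)^2) / 2 * (2 * pi / length(th_g))

  structure(list(
    image = rgb_image(out$noisy), clean = clean_img, mask = mask,
    spec = spec,
    expected = list(
      # for unperturbed, unbiased blobs the major-axis extent is exactly the
      # requested diameter; otherwise record the ground-truth raster extent
      diameter_mm = if (spec$asymmetry_bias == 0 &&
                          spec$boundary_noise_amp == 0) {
        spec$diameter_mm
      } else {
        diameter_mm(mask, calib)$m_mm
      },
      area_analytic_px = area_analytic,
      color_count = expected_counts,
      painted_colors = names(spec$colors),
      symmetric = spec$asymmetry_bias == 0
    )
  ), class = "synthetic_lesion")
}

#' Generate a reproducible suite of synthetic lesions
#'
#' Cycles through three archetypes designed to land in the three diagnostic
#' bands: a small symmetric single-colour mole (TDV well below 4.75), a
#' large shape-asymmetric brown mole (TDV inside the risk band), and a
#' large, irregular, two-colour, shape- and colour-asymmetric mole (TDV
#' above 5.45). Each fixture also carries the scores obtained by running
#' the feature stage on its clean render and ground-truth mask, plus the
#' diagnostic band they imply.
#'
#' @param n Number of fixtures (at least 1; all three bands are covered
#'   once `n >= 3`).
#' @param seed Master seed; fixture `i` uses `seed * 1000 + i`.
#' @param palette The [color_palette] used for painting and scoring.
#' @return A list of `n` `synthetic_lesion` objects whose `expected` record
#'   additionally holds `scores` (a, b, c, d on the clean render),
#'   `tdv_clean` and `category`.
#' @export
generate_suite <- function(n, seed = 1L, palette = default_palette()) {
  if (length(n) != 1L || n < 1L || n != round(n)) {
    abort_validation("n must be a positive integer")
  }
  archetypes <- list(
    low = function(fseed, j) lesion_spec(
      seed = fseed, diameter_mm = 2.5 + 0.25 * (j %% 4),
      eccentricity = 0.3, boundary_noise_amp = 0,
      asymmetry_bias = 0, colors = c(dark_brown = 1),
      hair_count = j %% 4L, noise_sigma = 3
    ),
    risk = function(fseed, j) lesion_spec(
      seed = fseed, diameter_mm = 9 + 0.5 * (j %% 3),
      eccentricity = 0.2, boundary_noise_amp = 0,
      asymmetry_bias = 0.4, colors = c(dark_brown = 1),
      hair_count = 1L + j %% 3L, noise_sigma = 3
    ),
    high = function(fseed, j) lesion_spec(
      seed = fseed, diameter_mm = 7 + 0.25 * (j %% 3),
      eccentricity = 0, boundary_noise_amp = 6, boundary_waves = 7L,
      asymmetry_bias = 0.5,
      colors = c(black = 0.5, dark_brown = 0.5), layout = "halves",
      hair_count = j %% 3L, noise_sigma = 3
    )
  )
  kinds <- rep(names(archetypes), length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fseed <- seed * 1000L + i
    spec <- archetypes[[kinds[i]]](fseed, i)
    lesion <- generate_lesion(spec, palette)
    feats <- compute_abcd(lesion$clean, lesion$mask,
                          calib = spec$calibration, palette = palette)
    res <- tdv_result(feats$a, feats$b, feats$c, feats$d)
    lesion$expected$scores <- c(a = feats$a, b = feats$b,
                                c = feats$c, d = feats$d)
    lesion$expected$m_mm_clean <- feats$diameter$m_mm
    lesion$expected$tdv_clean <- res$tdv
    lesion$expected$category <- res$category
    lesion$expected$archetype <- kinds[i]
    out[[i]] <- lesion
  }
  out
}
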