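# The six-colour clinical reference palette and its per-colour detection
# thresholds.

#' Colour reference palette
#'
#' A palette holds, for each clinically meaningful lesion colour, a set of
#' reference shades as normalised RGB triples, plus optional per-colour
#' threshold overrides. A colour is "present" in a lesion when the measured
#' distance to its reference shades falls at or below its threshold.
#'
#' @param shades Named list of numeric matrices (one row per reference
#'   shade, three columns, values in `[0, 1]`).
#' @param overrides Named numeric vector of per-colour threshold overrides;
#'   colours not listed get the default first-to-last-shade rule in
#'   [color_thresholds()].
#' @return An object of class `color_palette`.
#' @export
color_palette <- function(shades, overrides = numeric(0)) {
  if (!is.list(shades) || is.null(names(shades)) || any(names(shades) == "")) {
    abort_validation("palette shades must be a named list of matrices")
  }
  for (nm in names(shades)) {
    m <- shades[[nm]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) < 2L ||
        any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
      abort_validation(sprintf(
        "palette colour '%s' needs a matrix of >= 2 RGB rows in [0, 1]", nm
      ))
    }
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) ||
        !all(names(overrides) %in% names(shades))) {
      abort_validation("threshold overrides must be named after palette colours")
    }
    if (any(!is.finite(overrides)) || any(overrides <= 0)) {
      abort_validation("threshold overrides must be positive")
    }
  }
  structure(list(shades = shades, overrides = overrides),
            class = "color_palette")
}

#' Default six-colour palette
#'
#' Six colours (white, black, red, light brown, dark brown, bluish gray),
#' each with six reference shades normalised by 255. The red and
#' bluish-gray detection thresholds ship as fixed constants (0.818156 and
#' 0.415973); the remaining four follow the first-to-last-shade distance
#' rule of [color_thresholds()].
#'
#' @return A [color_palette].
#' @export
default_palette <- function() {
  sh <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  shades <- list(
    white = sh(1, 1, 1,
               0.9608, 0.9608, 0.9608,
               0.9216, 0.9216, 0.9216,
               0.8824, 0.8824, 0.8824,
               0.8431, 0.8431, 0.8431,
               0.8039, 0.8039, 0.8039),
    black = sh(0, 0, 0,
               0.0392, 0.0392, 0.0392,
               0.0784, 0.0784, 0.0784,
               0.1176, 0.1176, 0.1176,
               0.1569, 0.1569, 0.1569,
               0.1961, 0.1961, 0.1961),
    red = sh(0.7843, 0.5882, 0.3922,
             1, 0.1961, 0.1961,
             0.7843, 0, 0,
             0.7843, 0.1961, 0.1961,
             0.5882, 0, 0,
             0.5882, 0.1961, 0.1961),
    light_brown = sh(0.7843, 0.5882, 0.3922,
                     0.7843, 0.3922, 0,
                     0.7843, 0.3922, 0.1961,
                     0.5882, 0.3922, 0.1961,
                     0.5882, 0.3922, 0,
                     0.5882, 0.1961, 0),
    dark_brown = sh(0.5882, 0.3922, 0.3922,
                    0.4902, 0.2941, 0.2941,
                    0.3922, 0.1961, 0.1961,
                    0.3922, 0.1961, 0,
                    0.3922, 0, 0,
                    0.1961, 0, 0),
    bluish_gray = sh(0.5882, 0.4902, 0.5882,
                     0.4902, 0.4902, 0.5882,
                     0.3922, 0.3922, 0.4902,
                     0.3922, 0.4902, 0.5882,
                     0.1961, 0.3922, 0.5882,
                     0, 0.3922, 0.5882)
  )
  color_palette(shades,
                overrides = c(red = 0.818156, bluish_gray = 0.415973))
}

#' Per-colour detection thresholds
#'
#' Default rule: the Euclidean distance between a colour's first (lightest)
#' and last (darkest) reference shade. Colours with a configured override
#' use the override instead.
#'
#' @param palette A [color_palette].
#' @return Named numeric vector of thresholds, one per palette colour.
#' @export
color_thresholds <- function(palette) {
  stopifnot(inherits(palette, "color_palette"))
  vapply(names(palette$shades), function(nm) {
    ov <- palette$overrides[nm]
    if (length(ov) == 1L && !is.na(ov)) return(unname(ov))
    m <- palette$shades[[nm]]
    sqrt(sum((m[1, ] - m[nrow(m), ])^2))
  }, numeric(1))
}
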