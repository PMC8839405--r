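# JSON configuration: calibration, preprocessing, palette, thresholds and
# mode switches, merged over package defaults.

#' Default analysis configuration
#'
#' @return A nested list mirroring the JSON config schema: `calibration`,
#'   `preprocess`, `palette` (`NULL` = built-in), `thresholds`
#'   (`border_threshold`, `delta_a_frac`, `tdv_bands`) and `modes`
#'   (`color_distance`, `border_stat`, `acolor_agg`).
#' @export
default_config <- function() {
  list(
    calibration = list(width_px = 160, height_px = 120,
                       width_mm = 20, height_mm = 15),
    preprocess = list(median_radius = 1, close_radius = 2,
                      clip_low = NULL, clip_high = NULL),
    palette = NULL,
    thresholds = list(border_threshold = 15, delta_a_frac = 0.05,
                      tdv_bands = c(4.75, 5.45)),
    modes = list(color_distance = "mean", border_stat = "radius",
                 acolor_agg = "mean")
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load an analysis configuration from JSON
#'
#' Keys present in the file override the package defaults; everything else
#' keeps its default. A custom palette is given as
#' `palette = {shades: {<colour>: [[r,g,b], ...]}, overrides: {<colour>: t}}`.
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (is.list(path)) return(.merge_config(cfg, path))
  if (!file.exists(path)) abort_io(sprintf("cannot read config '%s'", path))
  user <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort_io(sprintf(
      "invalid JSON config '%s': %s", path, conditionMessage(e)
    ))
  )
  .merge_config(cfg, user)
}

# materialise R objects from a merged config list
.config_objects <- function(cfg) {
  cal <- do.call(calibration, cfg$calibration)
  pp <- preprocess_params(
    median_radius = cfg$preprocess$median_radius,
    close_radius = cfg$preprocess$close_radius,
    clip_low = cfg$preprocess$clip_low,
    clip_high = cfg$preprocess$clip_high
  )
  pal <- if (is.null(cfg$palette)) {
    default_palette()
  } else {
    shades <- lapply(cfg$palette$shades, function(s) {
      m <- if (is.matrix(s)) s else do.call(rbind, s)
      storage.mode(m) <- "numeric"
      m
    })
    ov <- unlist(cfg$palette$overrides %||% list())
    color_palette(shades, if (length(ov)) ov else numeric(0))
  }
  feat <- abcd_config(
    delta_a_frac = cfg$thresholds$delta_a_frac,
    acolor_agg = cfg$modes$acolor_agg,
    border_threshold = cfg$thresholds$border_threshold,
    border_stat = cfg$modes$border_stat,
    color_mode = cfg$modes$color_distance
  )
  list(calibration = cal, preprocess = pp, palette = pal, features = feat,
       bands = as.numeric(cfg$thresholds$tdv_bands))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
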