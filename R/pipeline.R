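# End-to-end analysis: load -> preprocess -> segment -> ABCD -> TDV ->
# diagnosis, with a JSON report, plus batch processing over a directory.

#' Analyse an in-memory image
#'
#' Core pipeline on an already-loaded [rgb_image]; [analyze()] wraps this
#' with file I/O.
#'
#' @param img An [rgb_image].
#' @param config `NULL`, a config list, or a JSON config path
#'   (see [load_config()]).
#' @return An analysis report (list) with preprocessing parameters,
#'   segmentation thresholds, all ABCD intermediates, the four scores, the
#'   TDV, the diagnostic category and its display message.
#' @export
analyze_image <- function(img, config = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  cfg <- load_config(config)
  obj <- .config_objects(cfg)
  pp <- .stage("preprocess", preprocess(img, obj$preprocess))
  th <- .stage("segmentation", multi_otsu(pp$gray))
  mask <- .stage("segmentation", extract_lesion_mask(pp$gray, th))
  feats <- compute_abcd(pp$rgb, mask, obj$calibration, obj$palette,
                        obj$features)
  res <- tdv_result(feats$a, feats$b, feats$c, feats$d, bands = obj$bands)
  list(
    preprocess = list(
      median_radius = obj$preprocess$median_radius,
      close_radius = obj$preprocess$close_radius,
      clip_low = unname(pp$clip["clip_low"]),
      clip_high = unname(pp$clip["clip_high"])
    ),
    segmentation = list(t1 = th$t1, t2 = th$t2, area_px = mask$area),
    intermediates = list(
      novl_lr = feats$asymmetry$novl_lr,
      novl_ud = feats$asymmetry$novl_ud,
      delta_a = feats$asymmetry$delta_a,
      acolor = feats$asymmetry$acolor,
      sector_std = feats$border$sector_std,
      cx = feats$color$cx,
      t0 = feats$color$t0,
      nr_x = feats$diameter$nr_x,
      nr_y = feats$diameter$nr_y,
      m_mm = feats$diameter$m_mm
    ),
    scores = list(a = feats$a, b = feats$b, c = feats$c, d = feats$d),
    tdv = res$tdv,
    category = res$category,
    message = res$message,
    tool_version = as.character(utils::packageVersion("dermabcd")),
    config_hash = .config_hash(cfg),
    mask = mask
  )
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Analyse a lesion photograph
#'
#' Full pipeline from an image file, optionally writing a JSON report and
#' the segmentation mask.
#'
#' @param path Image file (PNG/BMP/PPM/JPEG/TIFF).
#' @param config `NULL`, config list, or JSON config path.
#' @param out Optional path for the JSON report.
#' @param save_mask Optional path for the lesion mask as a 0/255 PNG.
#' @return The analysis report, invisibly; the report's `input` field holds
#'   the image path.
#' @export
analyze <- function(path, config = NULL, out = NULL, save_mask = NULL) {
  img <- .stage("load", load_image(path))
  report <- analyze_image(img, config)
  mask <- report$mask
  report$mask <- NULL
  report <- c(list(input = path), report)
  if (!is.null(save_mask)) {
    png::writePNG(matrix(as.numeric(mask$member), mask$height, mask$width),
                  save_mask)
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

#' Analyse every image in a directory
#'
#' Failures on individual files are recorded and the batch continues.
#'
#' @param dir Directory containing lesion images.
#' @param config `NULL`, config list, or JSON config path.
#' @param out Optional path for the CSV summary (filename, A, B, C, D,
#'   TDV, category).
#' @return A list with `summary` (data frame, one row per analysed image)
#'   and `failures` (named character vector of error messages).
#' @export
batch <- function(dir, config = NULL, out = NULL) {
  if (!dir.exists(dir)) abort_io(sprintf("no such directory '%s'", dir))
  files <- list.files(dir, pattern = "\\.(png|bmp|ppm|pgm|pnm|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    abort_validation(sprintf("directory '%s' contains no readable images", dir))
  }
  rows <- list()
  failures <- character(0)
  for (f in files) {
    rep <- tryCatch(analyze(f, config), error = function(e) e)
    if (inherits(rep, "error")) {
      failures[basename(f)] <- conditionMessage(rep)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      filename = basename(f),
      A = rep$scores$a, B = rep$scores$b, C = rep$scores$c, D = rep$scores$d,
      TDV = rep$tdv, category = rep$category,
      stringsAsFactors = FALSE
    )
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filename = character(0), A = numeric(0), B = integer(0),
               C = integer(0), D = numeric(0), TDV = numeric(0),
               category = character(0))
  if (!is.null(out)) utils::write.csv(summary, out, row.names = FALSE)
  list(summary = summary, failures = failures)
}
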