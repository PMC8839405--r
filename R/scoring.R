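# TDV combination, three-way diagnosis, and evaluation metrics.

.TDV_WEIGHTS <- c(a = 1.3, b = 0.1, c = 0.5, d = 0.5)
.TDV_BANDS <- c(4.75, 5.45)

.DIAGNOSIS_MESSAGES <- c(
  not_cancerous = "The mole is not cancerous, you are safe!",
  risk = "The mole could be cancerous, it should be checked by a doctor!",
  cancerous = "The mole is cancerous and must be checked by a doctor!"
)

#' Total dermatoscopic value
#'
#' Weighted combination of the four criterion scores:
#' `TDV = 1.3 A + 0.1 B + 0.5 C + 0.5 D`.
#'
#' @param a Asymmetry score in `[0, 2]`.
#' @param b Border score, integer in `[0, 8]`.
#' @param c Colour score, integer in `[1, 6]`.
#' @param d Diameter score in `[0.5, 5]`.
#' @return The TDV value (unrounded).
#' @export
tdv_score <- function(a, b, c, d) {
  chk <- function(val, lo, hi, nm, int = FALSE) {
    if (length(val) != 1L || !is.finite(val) || val < lo || val > hi ||
        (int && val != round(val))) {
      abort_validation(sprintf(
        "criterion %s = %s outside its range [%s, %s]%s",
        nm, format(val), format(lo), format(hi),
        if (int) " (integer)" else ""
      ))
    }
  }
  chk(a, 0, 2, "A")
  chk(b, 0, 8, "B", int = TRUE)
  chk(c, 1, 6, "C", int = TRUE)
  chk(d, 0.5, 5, "D")
  1.3 * a + 0.1 * b + 0.5 * c + 0.5 * d
}

#' Three-way diagnosis from the TDV
#'
#' `TDV < 4.75` is not cancerous, `4.75 <= TDV <= 5.45` presents a cancer
#' risk, and `TDV > 5.45` is cancerous; the bands partition the whole line
#' with both boundary values mapped to the risk band.
#'
#' @param tdv Non-negative TDV value.
#' @param bands Lower and upper band boundaries.
#' @return One of `"not_cancerous"`, `"risk"`, `"cancerous"`.
#' @export
classify <- function(tdv, bands = .TDV_BANDS) {
  if (length(tdv) != 1L || !is.finite(tdv) || tdv < 0) {
    abort_validation("tdv must be a non-negative number")
  }
  if (length(bands) != 2L || bands[1] > bands[2]) {
    abort_validation("bands must be two non-decreasing boundaries")
  }
  if (tdv < bands[1]) "not_cancerous" else if (tdv <= bands[2]) "risk" else "cancerous"
}

#' Display message for a diagnostic category
#'
#' @param category A category returned by [classify()].
#' @param messages Named character vector of display texts (localisable).
#' @return The display string.
#' @export
diagnosis_message <- function(category, messages = .DIAGNOSIS_MESSAGES) {
  if (!category %in% names(messages)) {
    abort_validation(sprintf("unknown category '%s'", category))
  }
  unname(messages[category])
}

#' Combined TDV result
#'
#' Convenience wrapper combining [tdv_score()], [classify()] and
#' [diagnosis_message()].
#'
#' @inheritParams tdv_score
#' @param bands Diagnostic band boundaries.
#' @param messages Display texts per category.
#' @return An object of class `tdv_result` with fields `a`, `b`, `c`, `d`,
#'   `tdv`, `category` and `message`.
#' @export
tdv_result <- function(a, b, c, d, bands = .TDV_BANDS,
                       messages = .DIAGNOSIS_MESSAGES) {
  tdv <- tdv_score(a, b, c, d)
  category <- classify(tdv, bands)
  structure(list(a = a, b = b, c = c, d = d, tdv = tdv,
                 category = category,
                 message = diagnosis_message(category, messages)),
            class = "tdv_result")
}

#' @export
print.tdv_result <- function(x, ...) {
  cat(sprintf("TDV = %.2f  (A=%.2f B=%d C=%d D=%.2f) -> %s\n%s\n",
              x$tdv, x$a, as.integer(x$b), as.integer(x$c), x$d,
              x$category, x$message))
  invisible(x)
}

#' Binary confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    abort_validation("confusion counts must be non-negative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Three-class confusion matrix
#'
#' Cross-tabulates true against predicted labels over the three diagnostic
#' classes. Rows are the reference (e.g. the specialist's diagnosis),
#' columns the system's prediction.
#'
#' @param truth,predicted Character vectors of class labels.
#' @param levels Class labels, in order.
#' @return A `length(levels)` square integer matrix.
#' @export
confusion_matrix <- function(truth, predicted,
                             levels = c("C1", "C2", "C3")) {
  if (length(truth) != length(predicted)) {
    abort_validation("truth and predicted must have the same length")
  }
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad)) {
    abort_validation(paste0("unknown labels: ", paste(bad, collapse = ", ")))
  }
  m <- table(factor(truth, levels), factor(predicted, levels))
  unclass(matrix(as.integer(m), nrow = length(levels),
                 dimnames = list(truth = levels, predicted = levels)))
}

#' Collapse a 3x3 confusion matrix to binary counts
#'
#' The positive class is "not cancerous": TP are positives predicted
#' positive, FN positives predicted into any other class (a cautious
#' "possibly cancerous" call on a benign mole counts as a false negative),
#' FP any non-positive predicted positive, TN the rest.
#'
#' @param m Square confusion matrix (rows = truth, columns = predicted).
#' @param positive Name of the positive class.
#' @return A [confusion_counts] object.
#' @export
collapse_confusion <- function(m, positive = "C1") {
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !positive %in% rownames(m)) {
    abort_validation("m must be a square named confusion matrix containing the positive class")
  }
  tp <- m[positive, positive]
  fn <- sum(m[positive, ]) - tp
  fp <- sum(m[, positive]) - tp
  tn <- sum(m) - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy, precision, recall and F1. Undefined ratios (division by zero)
#' are returned as `NA` rather than raising an error.
#'
#' @param counts A [confusion_counts] object (or a list/vector with
#'   elements `tp`, `tn`, `fp`, `fn`).
#' @return A list with `accuracy`, `precision`, `recall` and `f1`.
#' @export
evaluate <- function(counts) {
  cts <- as.list(counts)[c("tp", "tn", "fp", "fn")]
  if (any(vapply(cts, is.null, logical(1)))) {
    abort_validation("counts must provide tp, tn, fp and fn")
  }
  tp <- cts$tp; tn <- cts$tn; fp <- cts$fp; fn <- cts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) abort_validation("confusion counts are all zero")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = sdiv(tp + tn, total), precision = precision,
       recall = recall, f1 = f1)
}

#' Evaluate predictions stored in a CSV file
#'
#' The file needs columns `predicted_label` and `true_label` over the
#' classes C1 (not cancerous), C2 (cancerous), C3 (possibly cancerous).
#'
#' @param path CSV file path.
#' @param positive Positive class for the binary collapse.
#' @return A list with the 3x3 `matrix`, the collapsed `counts` and the
#'   `metrics`.
#' @export
evaluate_csv <- function(path, positive = "C1") {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("predicted_label", "true_label")
  if (!all(need %in% names(df))) {
    abort_validation("CSV needs columns predicted_label and true_label")
  }
  m <- confusion_matrix(df$true_label, df$predicted_label)
  counts <- collapse_confusion(m, positive)
  list(matrix = m, counts = counts, metrics = evaluate(counts))
}
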