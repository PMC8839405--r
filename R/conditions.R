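# Structured error conditions used across the pipeline. The CLI maps these
# classes onto distinct exit codes.

.abort <- function(message, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dermabcd_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

abort_validation <- function(message) {
  .abort(message, "dermabcd_validation_error", call = sys.call(-1))
}

abort_io <- function(message) {
  .abort(message, "dermabcd_io_error", call = sys.call(-1))
}

abort_segmentation <- function(message) {
  .abort(message, "dermabcd_segmentation_error", call = sys.call(-1))
}

# run a pipeline stage, prefixing failures with the stage name so callers
# can see where the chain broke
.stage <- function(name, expr) {
  tryCatch(
    expr,
    dermabcd_error = function(e) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      stop(e)
    }
  )
}
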