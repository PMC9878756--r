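# Classed conditions so callers can distinguish failure modes programmatically.

stop_ett <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("ett_", class), "ett_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @keywords internal
assert_that <- function(ok, class, message) {
  if (!isTRUE(ok)) stop_ett(class, message, call = sys.call(-1))
  invisible(TRUE)
}
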