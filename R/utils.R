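#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Errors are thrown with stop();
# recoverable oddities are reported with a classed message so callers and
# tests can distinguish them from ordinary chatter.

lrn_abort <- function(..., class = "lncregnet_error") {
  stop(errorCondition(paste0(...), class = c(class, "lncregnet_error")))
}

lrn_note <- function(...) {
  message("[lncregnet] ", ...)
}

#' @noRd
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) lrn_abort(...)
  invisible(TRUE)
}

# scale_tag transitions are one-way: raw -> log2 -> normalized
SCALE_LEVELS <- c(raw = 1L, log2 = 2L, normalized = 3L)

assert_scale <- function(x, allowed) {
  assert_that(x$scale_tag %in% allowed,
              "operation requires scale_tag in {", paste(allowed, collapse = ", "),
              "} but matrix is '", x$scale_tag, "'")
}
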