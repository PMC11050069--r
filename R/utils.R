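#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper pt rnbinom rnorm runif var p.adjust setNames
#'   ks.test
#' @importFrom utils read.delim write.table head
NULL

# Classed error so callers can distinguish validation failures from bugs.
stop_ploidysig <- function(msg, class = "ploidysig_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "ploidysig_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

assert_that <- function(ok, msg, class = "ploidysig_validation_error") {
  if (!isTRUE(ok)) stop_ploidysig(msg, class = class)
  invisible(TRUE)
}

# Fan a single user seed out into named, order-independent child seeds so
# each simulation component is reproducible in isolation.  Keeps children
# well below 2^31.
child_seed <- function(seed, component, index = 0L) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) %% 500000L) * 3571L + h * 127L + as.integer(index) * 7919L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
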