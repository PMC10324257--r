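#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils read.csv write.csv modifyList
NULL

# Abort with a classed condition so callers can distinguish domain errors
# (bad arguments, geometry violations) from I/O errors.
osm_stop <- function(msg, class = "osm_domain_error") {
  stop(errorCondition(msg, class = c(class, "osm_error")))
}

osm_check <- function(ok, msg, class = "osm_domain_error") {
  if (!isTRUE(ok)) osm_stop(msg, class = class)
  invisible(TRUE)
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this,
# which is what makes them pure functions of (input, seed).
with_seed <- function(seed, code) {
  osm_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed so that independent consumers of one
# user-facing seed do not share RNG streams. Kept inside 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 13217L + as.integer(stream) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))
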