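# Classed conditions so callers can branch on failure modes
# (e.g. a dish with no germination vs. a malformed table).

st_stop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "seedthresholds_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

st_warn <- function(subclass, message, ...) {
  warning(structure(
    class = c(subclass, "seedthresholds_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @importFrom stats coef lm median pt qnorm quantile rbinom rlnorm rnorm
#'   setNames approx cor complete.cases predict residuals
#' @importFrom utils read.csv write.csv
NULL
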