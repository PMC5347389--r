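#' @importFrom rlang abort warn .data
#' @importFrom stats coef optimize qt quantile rnorm runif sd setNames uniroot
#' @importFrom utils head
NULL

# shared input checks ---------------------------------------------------------

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", what),
          class = "mixray_domain_error")
  }
  invisible(x)
}

check_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what),
          class = "mixray_domain_error")
  }
  invisible(x)
}

# lg is used throughout for log10, matching the concentration scale the
# response models are parameterised on
lg <- function(x) log10(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
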