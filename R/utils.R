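#' @useDynLib cureterm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Overflow-safe logistic; plogis is already stable but keep one entry point
# so the incidence submodel and the generator share it.
logistic <- function(eta) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor in logistic()")
  stats::plogis(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer scalar", name))
  invisible(x)
}

# Reverse cumulative sum: out[i] = sum(v[i:n]).
revcumsum <- function(v) rev(cumsum(rev(v)))

# Two-sided normal p-value from a Wald z statistic.
wald_p <- function(z) 2 * stats::pnorm(-abs(z))
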