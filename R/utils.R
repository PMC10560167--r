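#' @importFrom stats complete.cases cor median p.adjust pf pnorm predict pt
#'   qf qnorm quantile rbinom rnorm runif sd smooth.spline wilcox.test
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardise a numeric vector to mean 0, SD 1
#'
#' Constant vectors are returned as all zeros rather than NaN.
#' @param x numeric vector (NAs preserved).
#' @return standardised vector.
#' @keywords internal
zscale <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_config(...)
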