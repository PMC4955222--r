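#' Right-continuous step function
#'
#' Light container for product-limit style estimators: jump times in ascending
#' order, the value attained at (and after) each jump, and the value before the
#' first jump.
#'
#' @param time ascending jump times.
#' @param value value right of each jump.
#' @param start_value value before the first jump.
#' @return an object of class `crs_stepfun`.
#' @export
crs_stepfun <- function(time, value, start_value) {
  stopifnot(length(time) == length(value), !is.unsorted(time, strictly = TRUE))
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 start_value = as.numeric(start_value)),
            class = "crs_stepfun")
}

#' Evaluate a step function
#'
#' @param sf a [crs_stepfun()].
#' @param t evaluation times.
#' @param left if `TRUE`, return the left-continuous limit f(t-).
#' @return numeric vector of values.
#' @export
step_eval <- function(sf, t, left = FALSE) {
  vals <- c(sf$start_value, sf$value)
  # findInterval with left.open gives the number of jump times < t (left) or
  # <= t (right-continuous evaluation)
  idx <- findInterval(t, sf$time, left.open = left)
  vals[idx + 1L]
}

#' @export
print.crs_stepfun <- function(x, ...) {
  cat(sprintf("step function: %d jumps, start %.4f, final %.4f\n",
              length(x$time), x$start_value,
              if (length(x$value)) x$value[length(x$value)] else x$start_value))
  invisible(x)
}

# survfit -> crs_stepfun for a single curve; col picks a pstate column for
# multi-state fits, NULL takes the survival curve.
survfit_to_stepfun <- function(fit, col = NULL, start_value = NULL) {
  if (is.null(col)) {
    v <- fit$surv
    if (is.null(start_value)) start_value <- 1
  } else {
    v <- fit$pstate[, col]
    if (is.null(start_value)) start_value <- 0
  }
  crs_stepfun(fit$time, v, start_value)
}
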