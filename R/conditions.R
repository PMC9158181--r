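#' Signal an undefined Sorensen-Dice statistic
#'
#' The Sorensen-Dice dissimilarity and, more often, its studentized version
#' are undefined on tables with certain zero cells: when
#' `n11 + n10 + n01 = 0` no dissimilarity can be formed at all, and when
#' `n11 = 0` or `n10 + n01 = 0` the estimated standard error is zero so the
#' studentized statistic does not exist. Such cases are signalled as a typed
#' condition so that callers (the bootstrap and simulation layers) can catch
#' them and decrement their effective replicate counts instead of aborting.
#'
#' @param message Condition message.
#' @param call Call to attach to the condition.
#' @return Does not return; throws a condition of class
#'   `sorequiv_undefined_statistic`.
#' @keywords internal
undefined_statistic <- function(message, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c("sorequiv_undefined_statistic", "sorequiv_error"),
                      call = call))
}

#' Test whether a condition is an undefined-statistic signal
#'
#' @param x A condition object (e.g. caught by [tryCatch()]).
#' @return `TRUE` if `x` carries the undefined-statistic class.
#' @examples
#' res <- tryCatch(sorensen_dissimilarity(0, 0, 0),
#'                 error = function(e) e)
#' is_undefined_statistic(res)
#' @export
is_undefined_statistic <- function(x) {
  inherits(x, "sorequiv_undefined_statistic")
}

# input-validation error, distinct from undefined-statistic
sq_input_error <- function(message, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c("sorequiv_input_error", "sorequiv_error"),
                      call = call))
}
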