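#' Construct a right-censored survival sample
#'
#' Bundles observed times `X_i = min(T_i, C_i)` and event indicators
#' `delta_i` (1 = event observed, 0 = censored) into a validated object
#' used by every estimator in the package.
#'
#' @param times Numeric vector of nonnegative observed times (any unit;
#'   the estimators are scale-free).
#' @param events Vector of event indicators coercible to 0/1 (numeric or
#'   logical); 1 means the event was observed, 0 means the observation
#'   was censored.
#' @return An object of class `"survival_sample"`: a list with elements
#'   `times`, `events` and `n`.
#' @examples
#' s <- survival_sample(c(1, 2, 3), c(1, 1, 0))
#' s$n
#' @export
survival_sample <- function(times, events) {
  if (is.logical(events)) events <- as.numeric(events)
  if (!is.numeric(times) || !is.numeric(events))
    stop("'times' and 'events' must be numeric", call. = FALSE)
  if (length(times) != length(events))
    stop("'times' and 'events' must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a survival sample needs at least 2 observations", call. = FALSE)
  if (anyNA(times) || anyNA(events))
    stop("missing values are not allowed; drop them before construction",
         call. = FALSE)
  if (any(times < 0)) {
    bad <- which(times < 0)[1L]
    stop(sprintf("negative time at position %d (%g)", bad, times[bad]),
         call. = FALSE)
  }
  if (!all(events %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)", call. = FALSE)
  structure(
    list(times = as.numeric(times), events = as.numeric(events),
         n = length(times)),
    class = "survival_sample"
  )
}

#' @export
print.survival_sample <- function(x, ...) {
  cat(sprintf("Right-censored survival sample: n = %d, events = %d, censored = %d\n",
              x$n, sum(x$events == 1), sum(x$events == 0)))
  cat(sprintf("  time range: [%g, %g]\n", min(x$times), max(x$times)))
  invisible(x)
}

as_survival_sample <- function(x) {
  if (inherits(x, "survival_sample")) return(x)
  stop("expected a 'survival_sample' object; see survival_sample()",
       call. = FALSE)
}
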