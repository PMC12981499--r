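#' Kaplan-Meier product-limit estimation and the plateau cure-rate estimator
#'
#' `fit_km()` computes the product-limit estimate of the survival function
#' S(t) from a right-censored sample. The resulting curve is a
#' right-continuous, non-increasing step function dropping only at observed
#' event times; ties between events and censorings at the same time are
#' resolved events-first (censored subjects remain in the risk set for
#' events at their own time), the standard convention.
#'
#' The plateau estimator of the cure rate is the curve evaluated at the
#' largest observed time t(n). It is consistent only when follow-up is
#' sufficient (censoring support extends past the uncured event-time
#' support); otherwise it overestimates the cure rate, which is what the
#' tail-corrected estimators in [estimate_cure_rate()] address.
#'
#' @param sample A [survival_sample()].
#' @return `fit_km()` returns an object of class `"km_curve"`: a list with
#'   `time` (strictly increasing event times with at least one event),
#'   `surv` (the estimate just after each drop), `n_risk`, `n_event`,
#'   `t_max` (largest observed time, event or censored), `p_n` (the curve
#'   value at `t_max`, i.e. the plateau estimate) and `n`.
#' @seealso [km_eval()], [km_cure_rate()], [km_profile()]
#' @examples
#' s <- survival_sample(c(1, 2, 3), c(1, 1, 0))
#' fit <- fit_km(s)
#' km_cure_rate(s)        # 1/3
#' km_eval(fit, 1.5)      # 2/3
#' @export
fit_km <- function(sample) {
  sample <- as_survival_sample(sample)
  .km(sample$times, sample$events)
}

# Bare fitting core: called tens of thousands of times by the bootstrap,
# so it avoids data frames and validation. times/events need not be sorted.
.km <- function(times, events) {
  n <- length(times)
  ord <- order(times)
  t_sorted <- times[ord]
  e_sorted <- events[ord]
  first <- !duplicated(t_sorted)
  ut <- t_sorted[first]                       # unique sorted times
  n_risk <- n - which(first) + 1L             # at risk just before each ut
  d <- unname(rowsum(e_sorted, cumsum(first), reorder = FALSE)[, 1L])  # events per ut
  surv_all <- cumprod(1 - d / n_risk)
  keep <- d > 0
  structure(
    list(time = ut[keep], surv = surv_all[keep],
         n_risk = n_risk[keep], n_event = d[keep],
         t_max = ut[length(ut)],
         p_n = surv_all[length(surv_all)],
         n = n),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d distinct event times, t(n) = %g\n",
              x$n, length(x$time), x$t_max))
  cat(sprintf("  plateau estimate S(t(n)) = %.4f\n", x$p_n))
  invisible(x)
}

# Right-continuous step evaluation without validation; t may be a vector.
.km_eval <- function(curve, t) {
  i <- findInterval(t, curve$time)
  c(1, curve$surv)[i + 1L]
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation: the value at `t` is the product over
#' all drop times `<= t`, so a time exactly at a drop returns the
#' post-drop value. Times before the first event return 1; times beyond
#' the largest observed time return the plateau value (constant
#' extension).
#'
#' @param curve A `"km_curve"` from [fit_km()].
#' @param t Numeric vector of nonnegative evaluation times.
#' @return Numeric vector of survival probabilities in \[0, 1\].
#' @export
km_eval <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("evaluation times must be nonnegative numbers", call. = FALSE)
  .km_eval(curve, t)
}

#' Plateau (Kaplan-Meier) cure-rate estimate
#'
#' The Kaplan-Meier survival estimate at the largest observed time t(n).
#' Equals 0 when the largest observation is an event; under purely
#' administrative (type-I) censoring it equals the censored fraction.
#'
#' @inheritParams fit_km
#' @return A single probability.
#' @export
km_cure_rate <- function(sample) {
  fit_km(sample)$p_n
}

#' Profile of the Kaplan-Meier estimate at fractions of the largest time
#'
#' Evaluates the fitted curve at `y * t(n)` for each fraction `y`,
#' which shows how flat the tail of the curve is: a near-constant profile
#' indicates a long plateau (adequate follow-up), a decreasing one
#' indicates mass still falling near the end of follow-up. The row at
#' `y = 1` equals the plateau cure-rate estimate.
#'
#' @inheritParams fit_km
#' @param y_grid Fractions in (0, 1]; default `c(0.6, 0.7, 0.8, 0.9,
#'   0.92, 0.94, 0.96, 0.98, 1.0)`.
#' @return A data frame with columns `y` and `surv` (values non-increasing
#'   in `y`).
#' @export
km_profile <- function(sample,
                       y_grid = c(0.6, 0.7, 0.8, 0.9, 0.92, 0.94, 0.96,
                                  0.98, 1.0)) {
  if (!is.numeric(y_grid) || any(y_grid <= 0) || any(y_grid > 1))
    stop("'y_grid' values must lie in (0, 1]", call. = FALSE)
  curve <- fit_km(sample)
  data.frame(y = y_grid, surv = .km_eval(curve, y_grid * curve$t_max))
}
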