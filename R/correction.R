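#' Tuning-parameter grid for the tail correction
#'
#' The candidate fractions y at which the tail correction is evaluated.
#' The default grid is \{0.60, 0.62, ..., 0.98\} (20 values, step 0.02),
#' the grid used in the extreme-value bootstrap correction literature.
#'
#' @param from,to,by Grid bounds and step; all values must lie strictly
#'   inside (0, 1).
#' @return Numeric vector of class `"correction_grid"`, strictly
#'   increasing.
#' @export
correction_grid <- function(from = 0.60, to = 0.98, by = 0.02) {
  values <- seq(from, to, by = by)
  if (any(values <= 0) || any(values >= 1))
    stop("grid values must lie strictly inside (0, 1)", call. = FALSE)
  if (length(values) < 1L || is.unsorted(values, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  structure(values, class = "correction_grid")
}

as_correction_grid <- function(grid) {
  if (inherits(grid, "correction_grid")) return(as.numeric(grid))
  if (is.numeric(grid) && length(grid) >= 1L &&
      all(grid > 0) && all(grid < 1) && !is.unsorted(grid, strictly = TRUE))
    return(as.numeric(grid))
  stop("invalid correction grid; see correction_grid()", call. = FALSE)
}

#' Extreme-value tail ratio of a Kaplan-Meier curve
#'
#' The ratio
#' \deqn{\hat y^\gamma = \frac{\hat S(y t_{(n)}) - \hat S(y^2 t_{(n)})}
#'                            {\hat S(t_{(n)}) - \hat S(y t_{(n)})}}
#' estimating the geometric decay of the survival-curve tail: it compares
#' the mass lost over \eqn{[y^2 t_{(n)}, y t_{(n)}]} with the mass lost
#' over \eqn{[y t_{(n)}, t_{(n)}]}. For an exponential tail the ratio
#' exceeds 1. When the curve is flat on \eqn{[y t_{(n)}, t_{(n)}]} the
#' denominator is 0 and the ratio is undefined, returned as `NA`.
#'
#' @param curve A `"km_curve"` from [fit_km()].
#' @param y A single fraction in (0, 1).
#' @return A nonnegative number, or `NA` when the denominator is exactly 0.
#' @export
gamma_ratio <- function(curve, y) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y <= 0 || y >= 1)
    stop("'y' must be a single fraction in (0, 1)", call. = FALSE)
  s <- .km_eval(curve, c(y * curve$t_max, y^2 * curve$t_max))
  den <- curve$p_n - s[1L]
  if (den == 0) return(NA_real_)
  (s[1L] - s[2L]) / den
}

# Vectorized corrected estimates over a whole grid. Returns parallel
# vectors; `term` is the clamped quantity subtracted from the plateau
# estimate. The substitution rules, in order:
#   (i)  tail ratio undefined (0/0) or exactly 1 -> term 0;
#   (ii) term < 0 -> 0;  (iii) term > 1 -> 1;
#   then estimate = p_n - term, clamped into [0, 1].
# The same rules apply on the original sample and inside every bootstrap
# resample.
.corrected_grid <- function(curve, ygrid) {
  t_max <- curve$t_max
  p_n <- curve$p_n
  s_y <- .km_eval(curve, ygrid * t_max)
  s_y2 <- .km_eval(curve, ygrid^2 * t_max)
  den <- p_n - s_y
  gamma <- ifelse(den == 0, NA_real_, (s_y - s_y2) / den)
  undef <- is.na(gamma) | gamma == 1
  term_raw <- ifelse(undef, 0, (s_y - p_n) / (gamma - 1))
  term <- pmin(pmax(term_raw, 0), 1)
  estimate <- pmin(pmax(p_n - term, 0), 1)
  list(y = ygrid, gamma = gamma, term_raw = term_raw, term = term,
       estimate = estimate,
       flags = cbind(gamma_undefined   = undef,
                     term_clamped_low  = !undef & term_raw < 0,
                     term_clamped_high = !undef & term_raw > 1,
                     estimate_clamped_low  = p_n - term < 0,
                     estimate_clamped_high = p_n - term > 1))
}

#' Tail-corrected cure-rate estimate for a fixed tuning fraction
#'
#' Computes the corrected estimate
#' \deqn{\hat p_y = \hat p_n -
#'   \frac{\hat S(y t_{(n)}) - \hat S(t_{(n)})}{\hat y^\gamma - 1}}
#' where \eqn{\hat p_n} is the plateau estimate and \eqn{\hat y^\gamma}
#' the [gamma_ratio()]. The subtracted quantity (the correction term) is
#' substituted by 0 when it cannot be computed (undefined or unit tail
#' ratio) or is negative, capped at 1 when it exceeds 1, and the final
#' estimate is clamped into \[0, 1\]. With a geometrically decaying tail
#' the ratio exceeds 1 and the term is positive, so the correction pulls
#' the (over-)estimate downward.
#'
#' @inheritParams gamma_ratio
#' @return A list of class `"corrected_value"` with elements `y`,
#'   `gamma_ratio`, `term_raw` (unclamped subtracted quantity), `term`
#'   (after substitution rules), `estimate`, and logical `flags`
#'   (`gamma_undefined`, `term_clamped_low`, `term_clamped_high`,
#'   `estimate_clamped_low`, `estimate_clamped_high`).
#' @export
corrected_estimate <- function(curve, y) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y <= 0 || y >= 1)
    stop("'y' must be a single fraction in (0, 1)", call. = FALSE)
  g <- .corrected_grid(curve, y)
  structure(
    list(y = y, gamma_ratio = g$gamma[1L], term_raw = g$term_raw[1L],
         term = g$term[1L], estimate = g$estimate[1L],
         flags = as.list(g$flags[1L, ])),
    class = "corrected_value"
  )
}

#' Bootstrap draws of the tail-corrected estimate
#'
#' Nonparametric bootstrap: pairs (time, indicator) are resampled with
#' replacement, size n. For each resample j the corrected estimates
#' \eqn{\hat p^{(j)}_y} are computed over the grid and the draw is kept
#' only if some y strictly improves on the resample's plateau estimate
#' \eqn{\hat p^{(j)}_n}; the retained value is \eqn{\hat p^{(j)}_{y(j)}}
#' at \eqn{y(j) = \sup\{y \in H : \hat p^{(j)}_y < \hat p^{(j)}_n\}}.
#' Resamples with a flat tail (no y qualifies) are rejected and redrawn.
#' Drawing stops at `nb` accepted draws or `max_attempts` resamples,
#' whichever comes first, with a warning when the cap binds.
#'
#' Uses the current RNG state; seed the session (or use the `seed`
#' argument of [estimate_cure_rate()]) for reproducibility.
#'
#' @param sample A [survival_sample()].
#' @param grid A [correction_grid()] (or strictly increasing numeric
#'   vector in (0,1)).
#' @param nb Target number of accepted draws (default 200).
#' @param max_attempts Cap on total resamples, default `20 * nb`.
#' @return A list of class `"bootstrap_draws"`: `values` (accepted
#'   \eqn{\hat p^{(j)}_{y(j)}}), `selected_y`, `n_attempts`, `nb`.
#' @export
bootstrap_draws <- function(sample, grid = correction_grid(), nb = 200,
                            max_attempts = 20 * nb) {
  sample <- as_survival_sample(sample)
  ygrid <- as_correction_grid(grid)
  if (!is.numeric(nb) || nb < 2)
    stop("'nb' must be at least 2", call. = FALSE)
  times <- sample$times
  events <- sample$events
  n <- sample$n
  values <- numeric(nb)
  selected <- numeric(nb)
  accepted <- 0L
  attempts <- 0L
  while (accepted < nb && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- sample.int(n, n, replace = TRUE)
    curve <- .km(times[idx], events[idx])
    # cheap pre-check: no drop inside (y_min * t(n), t(n)] means the
    # corrected estimate cannot fall below the plateau for any y
    if (!any(curve$time > ygrid[1L] * curve$t_max)) next
    est <- .corrected_grid(curve, ygrid)$estimate
    ok <- which(est < curve$p_n)
    if (length(ok) == 0L) next
    accepted <- accepted + 1L
    j <- ok[length(ok)]                       # sup: largest qualifying y
    values[accepted] <- est[j]
    selected[accepted] <- ygrid[j]
  }
  if (accepted < nb)
    warning(sprintf(
      "only %d of %d bootstrap draws accepted after %d attempts (flat tail)",
      accepted, nb, attempts), call. = FALSE)
  structure(
    list(values = values[seq_len(accepted)],
         selected_y = selected[seq_len(accepted)],
         n_attempts = attempts, nb = nb),
    class = "bootstrap_draws"
  )
}

#' Aggregate bootstrap draws by mean or median
#'
#' The mean aggregator defines the EK estimator; the median aggregator
#' (for an even count m, the average of the m/2-th and (m/2+1)-th order
#' statistics; for odd m the middle order statistic) defines the EC
#' estimator and has breakdown point 1/2 against outlying draws, versus 0
#' for the mean.
#'
#' @param draws A `"bootstrap_draws"` object or a numeric vector of draw
#'   values.
#' @param method `"mean"` or `"median"`.
#' @return A single number.
#' @export
aggregate_draws <- function(draws, method = c("mean", "median")) {
  method <- match.arg(method)
  values <- if (inherits(draws, "bootstrap_draws")) draws$values else draws
  if (!is.numeric(values) || length(values) < 1L)
    stop("no draws to aggregate", call. = FALSE)
  if (method == "mean") return(mean(values))
  x <- sort(values)
  m <- length(x)
  if (m %% 2L == 0L) (x[m %/% 2L] + x[m %/% 2L + 1L]) / 2 else x[(m + 1L) %/% 2L]
}

#' Select the tuning fraction matching a bootstrap aggregate
#'
#' On the original sample's curve, evaluates the corrected estimate at
#' every grid fraction and returns the fraction whose estimate is closest
#' to the aggregated bootstrap value `g_value` (argmin of the absolute
#' difference); ties are broken by the smallest fraction.
#'
#' @inheritParams gamma_ratio
#' @param grid A [correction_grid()].
#' @param g_value Aggregated bootstrap value in \[0, 1\].
#' @return A list with `y_star` and `estimate` (the corrected estimate at
#'   `y_star`).
#' @export
select_y_star <- function(curve, grid = correction_grid(), g_value) {
  stopifnot(inherits(curve, "km_curve"))
  ygrid <- as_correction_grid(grid)
  if (!is.numeric(g_value) || length(g_value) != 1L || is.na(g_value))
    stop("'g_value' must be a single number", call. = FALSE)
  est <- .corrected_grid(curve, ygrid)$estimate
  i <- which.min(abs(est - g_value))          # first minimum = smallest y
  list(y_star = ygrid[i], estimate = est[i])
}

# Compute several estimators on one sample, sharing a single set of
# bootstrap draws between EK and EC (they differ only in the aggregator).
.estimate_all <- function(sample, methods, nb, grid, max_attempts = 20 * nb) {
  ygrid <- as_correction_grid(grid)
  curve <- .km(sample$times, sample$events)
  out <- list()
  if ("km" %in% methods)
    out$km <- list(method = "KM", estimate = curve$p_n, y_star = NA_real_,
                   g_value = NA_real_, draws = NULL)
  boot_methods <- intersect(methods, c("ek", "ec"))
  if (length(boot_methods)) {
    draws <- bootstrap_draws(sample, ygrid, nb = nb,
                             max_attempts = max_attempts)
    for (m in boot_methods) {
      if (length(draws$values) == 0L) {
        # no resample admitted a strict downward correction: fall back to
        # the uncorrected plateau estimate
        out[[m]] <- list(method = toupper(m), estimate = curve$p_n,
                         y_star = NA_real_, g_value = NA_real_,
                         draws = draws)
        next
      }
      g <- aggregate_draws(draws, if (m == "ek") "mean" else "median")
      sel <- select_y_star(curve, ygrid, g)
      out[[m]] <- list(method = toupper(m), estimate = sel$estimate,
                       y_star = sel$y_star, g_value = g, draws = draws)
    }
  }
  out
}

#' Estimate the cure rate from right-censored data
#'
#' The package's main entry point. Three estimators:
#' \describe{
#'   \item{KM}{the Kaplan-Meier plateau estimate \eqn{\hat S_n(t_{(n)})} —
#'     no correction.}
#'   \item{EK}{the tail-corrected estimate with the tuning fraction
#'     selected by matching the \emph{mean} of the bootstrap draws.}
#'   \item{EC}{as EK but matching the \emph{median} of the bootstrap
#'     draws, which is robust to a skewed or outlier-laden bootstrap
#'     distribution.}
#' }
#'
#' @param sample A [survival_sample()].
#' @param method `"km"`, `"ek"` or `"ec"`.
#' @param nb Number of accepted bootstrap draws (default 200); ignored
#'   for `"km"`.
#' @param grid A [correction_grid()].
#' @param seed Optional integer seed; when supplied the call is fully
#'   reproducible and the seed is recorded in the result.
#' @return A list of class `"cure_estimate"`: `method`, `estimate`,
#'   `y_star`, `g_value`, `draws` (a `"bootstrap_draws"` object, `NULL`
#'   for KM) and `seed`.
#' @examples
#' set.seed(7)
#' s <- simulate_sample(scenario_config("A", p = 0.3, n = 200))
#' estimate_cure_rate(s, "km")$estimate
#' estimate_cure_rate(s, "ec", nb = 50, seed = 1)$estimate
#' @export
estimate_cure_rate <- function(sample, method = c("km", "ek", "ec"),
                               nb = 200, grid = correction_grid(),
                               seed = NULL) {
  sample <- as_survival_sample(sample)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  res <- .estimate_all(sample, method, nb = nb, grid = grid)[[method]]
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(res) <- "cure_estimate"
  res
}

#' @export
print.cure_estimate <- function(x, ...) {
  cat(sprintf("%s cure-rate estimate: %.4f\n", x$method, x$estimate))
  if (!is.na(x$y_star))
    cat(sprintf("  y* = %.2f, bootstrap aggregate g = %.4f (%d draws, %d attempts)\n",
                x$y_star, x$g_value, length(x$draws$values),
                x$draws$n_attempts))
  invisible(x)
}
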