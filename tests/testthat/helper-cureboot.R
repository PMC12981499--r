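# Build a Kaplan-Meier-shaped step curve directly from (time, surv) pairs,
# bypassing fitting. Used to feed the tail-correction operations exactly
# specified survival values (hand-arithmetic oracles and closed-form
# curves).
make_curve <- function(time, surv, t_max = max(time)) {
  stopifnot(!is.unsorted(time, strictly = TRUE),
            !is.unsorted(rev(surv)), all(surv >= 0), all(surv <= 1))
  structure(
    list(time = time, surv = surv,
         n_risk = rep(NA_integer_, length(time)),
         n_event = rep(NA_integer_, length(time)),
         t_max = t_max, p_n = surv[length(surv)], n = NA_integer_),
    class = "km_curve"
  )
}

# Random censored sample: exponential event times against uniform
# censoring, guaranteeing a mix of events and censorings.
random_censored_sample <- function(n, rate = 1, cmax = 2) {
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, cmax)
  survival_sample(pmin(t_event, t_cens), as.numeric(t_event <= t_cens))
}
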