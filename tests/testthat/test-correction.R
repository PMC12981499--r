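test_that("tail ratio matches hand arithmetic and closed-form oracles", {
  # hand case: S(y^2 t)=0.30, S(y t)=0.26, S(t)=0.24 with t_max=1, y=0.5
  curve <- make_curve(c(0.2, 0.4, 0.9), c(0.30, 0.26, 0.24), t_max = 1)
  expect_equal(gamma_ratio(curve, 0.5), (0.26 - 0.30) / (0.24 - 0.26))

  # flat tail: 0/0 is undefined, not an error
  flat <- make_curve(c(0.1), c(0.4), t_max = 1)
  expect_true(is.na(gamma_ratio(flat, 0.8)))

  # exponential-tail closed form: S(t) = 0.2 + 0.8 exp(-0.0013 t),
  # evaluated on a dense step grid so the three step values are exact
  lam <- 0.0013; tmax <- 3000; y <- 0.8
  tt <- seq(1, tmax, by = 1)
  curve_exp <- make_curve(tt, 0.2 + 0.8 * exp(-lam * tt), t_max = tmax)
  oracle <- (exp(-lam * y * tmax) - exp(-lam * y^2 * tmax)) /
            (exp(-lam * tmax) - exp(-lam * y * tmax))
  expect_equal(gamma_ratio(curve_exp, y), oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.600, tolerance = 1e-3)
  expect_gt(gamma_ratio(curve_exp, y), 1)   # decaying tail => ratio > 1

  expect_error(gamma_ratio(curve, 1), "in \\(0, 1\\)")
  expect_error(gamma_ratio(curve, 0), "in \\(0, 1\\)")
})

test_that("corrected estimate applies the substitution rules in order", {
  # decaying tail, ratio 2: subtract (S(yt)-S(t))/(ratio-1) = 0.02
  c1 <- make_curve(c(0.2, 0.4, 0.9), c(0.30, 0.26, 0.24), t_max = 1)
  v1 <- corrected_estimate(c1, 0.5)
  expect_equal(v1$gamma_ratio, 2.0)
  expect_equal(v1$term, 0.02)
  expect_equal(v1$estimate, 0.22)
  expect_false(v1$flags$gamma_undefined)

  # undefined ratio (flat between y t and t): no correction
  c2 <- make_curve(c(0.2, 0.4), c(0.56, 0.38), t_max = 1)  # S(yt)=S(t)=0.38
  v2 <- corrected_estimate(c2, 0.5)
  expect_true(v2$flags$gamma_undefined)
  expect_equal(v2$term, 0)
  expect_equal(v2$estimate, 0.38)

  # ratio 2 branch: S(y^2 t)=0.56, S(yt)=0.44, S(t)=0.38 -> subtract 0.06
  c3 <- make_curve(c(0.2, 0.4, 0.9), c(0.56, 0.44, 0.38), t_max = 1)
  v3 <- corrected_estimate(c3, 0.5)
  expect_equal(v3$gamma_ratio, 2.0)
  expect_equal(v3$estimate, 0.32)

  # ratio 1/2 branch: raw term negative -> substituted by 0, no correction
  c4 <- make_curve(c(0.2, 0.4, 0.9), c(0.47, 0.44, 0.38), t_max = 1)
  v4 <- corrected_estimate(c4, 0.5)
  expect_equal(v4$gamma_ratio, 0.5)
  expect_equal(v4$term_raw, -0.12)
  expect_true(v4$flags$term_clamped_low)
  expect_equal(v4$term, 0)
  expect_equal(v4$estimate, 0.38)

  # ratio exactly 1 divides by zero -> treated as incalculable
  c5 <- make_curve(c(0.2, 0.4, 0.9), c(0.50, 0.44, 0.38), t_max = 1)
  v5 <- corrected_estimate(c5, 0.5)
  expect_equal(v5$gamma_ratio, 1.0)
  expect_true(v5$flags$gamma_undefined)
  expect_equal(v5$estimate, 0.38)

  # term capped at 1, then the estimate clamps at 0
  c7 <- make_curve(c(0.2, 0.4, 0.9), c(0.95, 0.50, 0.10), t_max = 1)
  v7 <- corrected_estimate(c7, 0.5)   # ratio 1.125, term 3.2 -> capped at 1
  expect_true(v7$flags$term_clamped_high)
  expect_equal(v7$term, 1)
  expect_true(v7$flags$estimate_clamped_low)
  expect_equal(v7$estimate, 0)
})

test_that("aggregators implement the mean and order-statistic median", {
  expect_equal(aggregate_draws(c(0.1, 0.2, 0.3, 0.9), "mean"), 0.375)
  expect_equal(aggregate_draws(c(0.1, 0.2, 0.3, 0.9), "median"), 0.25)
  expect_equal(aggregate_draws(c(0.3, 0.3, 0.3), "median"), 0.3)
  # even count: average of the m/2-th and (m/2+1)-th order statistics,
  # regardless of input order
  x <- c(0.9, 0.1, 0.4, 0.2, 0.35, 0.05)
  expect_equal(aggregate_draws(x, "median"), (0.2 + 0.35) / 2)
  expect_equal(aggregate_draws(x, "median"), stats::median(x))
  expect_error(aggregate_draws(numeric(0), "mean"), "no draws")
})

test_that("median aggregator resists contamination that shifts the mean", {
  set.seed(77)
  clean <- runif(200, 0.35, 0.45)
  spread <- diff(range(clean))
  contaminated <- clean
  contaminated[1:98] <- 0                    # 49% of draws zeroed out
  med_shift <- abs(aggregate_draws(clean, "median") -
                   aggregate_draws(contaminated, "median"))
  mean_shift <- abs(aggregate_draws(clean, "mean") -
                    aggregate_draws(contaminated, "mean"))
  expect_lt(med_shift, spread)
  # mean shifts by exactly the removed mass: sum of zeroed values / count
  expect_equal(mean_shift, sum(clean[1:98]) / 200, tolerance = 1e-12)
  expect_gt(mean_shift, 2 * med_shift)
})

test_that("mean-median gap of the draws predicts the EK-EC direction", {
  # left-skewed draws: mean < median, so the mean aggregator matches a
  # lower corrected estimate than the median aggregator
  curve <- fit_km(survival_sample(
    c(seq(100, 2900, by = 100), rep(3000, 15)),
    c(rep(1, 29), rep(0, 15))))
  grid <- correction_grid()
  skewed <- c(rep(0.05, 30), rep(0.30, 170))
  g_mean <- aggregate_draws(skewed, "mean")
  g_med <- aggregate_draws(skewed, "median")
  expect_lt(g_mean, g_med)
  est_mean <- select_y_star(curve, grid, g_mean)$estimate
  est_med <- select_y_star(curve, grid, g_med)$estimate
  expect_lte(est_mean, est_med)

  # symmetric draws: the two aggregators agree, so do the estimates
  sym <- seq(0.2, 0.4, length.out = 200)
  expect_equal(aggregate_draws(sym, "mean"), aggregate_draws(sym, "median"))
  expect_equal(select_y_star(curve, grid, aggregate_draws(sym, "mean")),
               select_y_star(curve, grid, aggregate_draws(sym, "median")))
})

test_that("y* minimizes the distance to the aggregate, smallest y on ties", {
  # flat tail: every corrected estimate equals the plateau -> smallest y
  flat <- make_curve(c(0.1), c(0.4), t_max = 1)
  sel <- select_y_star(flat, correction_grid(), g_value = 0.2)
  expect_equal(sel$y_star, 0.60)
  expect_equal(sel$estimate, 0.4)

  # constructed 3-point grid with g equidistant from two estimates
  grid3 <- c(0.5, 0.7, 0.9)
  curve <- fit_km(survival_sample(
    c(seq(100, 2900, by = 100), rep(3000, 15)),
    c(rep(1, 29), rep(0, 15))))
  est <- vapply(grid3, function(y) corrected_estimate(curve, y)$estimate,
                numeric(1))
  stopifnot(length(unique(est)) >= 2)        # fixture sanity
  two <- sort(unique(est))[1:2]
  g_mid <- mean(two)
  sel2 <- select_y_star(curve, grid3, g_mid)
  candidates <- grid3[abs(est - g_mid) == min(abs(est - g_mid))]
  expect_equal(sel2$y_star, min(candidates))
})

test_that("bootstrap draws satisfy the strict-improvement condition", {
  set.seed(12)
  s <- simulate_sample(scenario_config("A", p = 0.3, n = 300))
  p_n <- km_cure_rate(s)
  set.seed(1)
  d <- bootstrap_draws(s, nb = 50)
  expect_length(d$values, 50)
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_true(all(d$selected_y %in% as.numeric(correction_grid())))
  # decaying tail: nearly every resample qualifies
  expect_lt(d$n_attempts, 60)
  # draws are centered below the original plateau estimate
  expect_lt(mean(d$values), p_n)

  # perfectly flat tail: the strict inequality can never hold
  flat_s <- survival_sample(c(rep(1, 5), rep(10, 20)),
                            c(rep(1, 5), rep(0, 20)))
  expect_warning(d0 <- bootstrap_draws(flat_s, nb = 10, max_attempts = 40),
                 "flat tail")
  expect_length(d0$values, 0)
})

test_that("estimation is deterministic given a seed and respects [0,1]", {
  set.seed(8)
  s <- simulate_sample(scenario_config("A", p = 0.4, n = 200))
  e1 <- estimate_cure_rate(s, "ec", nb = 60, seed = 42)
  e2 <- estimate_cure_rate(s, "ec", nb = 60, seed = 42)
  expect_identical(e1, e2)
  e3 <- estimate_cure_rate(s, "ek", nb = 60, seed = 42)
  expect_identical(e1$draws, e3$draws)       # same resamples, new aggregator
  expect_true(e1$y_star %in% as.numeric(correction_grid()))

  # KM method delegates to the plateau estimator
  expect_equal(estimate_cure_rate(s, "km")$estimate, km_cure_rate(s))

  # fuzz degenerate samples: estimates always land in [0, 1], no errors
  set.seed(99)
  for (i in 1:15) {
    kind <- i %% 3
    s_f <- if (kind == 0) {
      survival_sample(rep(5, 10), rep(0, 10))             # all identical, censored
    } else if (kind == 1) {
      survival_sample(sample(c(1, 1, 2, 3000), 12, TRUE),
                      sample(0:1, 12, TRUE))              # heavy ties
    } else {
      random_censored_sample(8)
    }
    for (m in c("km", "ek", "ec")) {
      e <- suppressWarnings(
        estimate_cure_rate(s_f, m, nb = 20, seed = i))
      expect_true(e$estimate >= 0 && e$estimate <= 1)
    }
  }
})

test_that("with sufficient follow-up the correction nearly vanishes", {
  # events exhausted long before the horizon: corrected and plateau
  # estimates agree to within Monte-Carlo noise
  set.seed(314)
  diffs <- replicate(25, {
    s <- simulate_sample(scenario_config("C", p = 0.2, n = 400))
    ests <- suppressWarnings(
      estimate_cure_rate(s, "ec", nb = 50, seed = sample.int(1e6, 1)))
    ests$estimate - km_cure_rate(s)
  })
  expect_lt(abs(mean(diffs)), 0.01)
})
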