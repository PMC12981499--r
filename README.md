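# cureboot

Nonparametric cure-rate estimation from right-censored survival data when
follow-up may be insufficient — for biostatisticians analysing clinical
trials whose Kaplan–Meier curve ends in a long censored plateau.

## The problem and the estimators

Under the mixture cure model a fraction *p* of subjects never experiences
the event:

    S(t) = p + (1 − p) S₀(t),   0 < p < 1,

where S₀ is the survival function of the uncured. The natural
nonparametric estimate of *p* is the Kaplan–Meier plateau

    p̂ₙ = Ŝₙ(t₍ₙ₎),

the product-limit estimate at the largest observed time t₍ₙ₎. It is
consistent only when follow-up is sufficient (the censoring horizon
covers the uncured event-time support); otherwise it estimates S at the
horizon and **overestimates** *p*.

The tail-corrected estimator subtracts an extreme-value extrapolation of
the unobserved tail:

    p̂ᵧ = p̂ₙ − [Ŝₙ(y t₍ₙ₎) − Ŝₙ(t₍ₙ₎)] / (ŷ^γ − 1),

    ŷ^γ = [Ŝₙ(y t₍ₙ₎) − Ŝₙ(y² t₍ₙ₎)] / [Ŝₙ(t₍ₙ₎) − Ŝₙ(y t₍ₙ₎)],

with tuning fraction y ∈ (0,1) chosen from the grid
H = {0.60, 0.62, …, 0.98} by bootstrap: each resample j contributes its
corrected estimate at y(j) = sup{y ∈ H : p̂ᵧ⁽ʲ⁾ < p̂ₙ⁽ʲ⁾}, the Nb = 200
accepted draws are aggregated by a statistic g, and

    y* = argmin_{y ∈ H} | p̂ᵧ − g |.

Aggregating by the **mean** gives the EK estimator; aggregating by the
**median** (average of the Nb/2-th and (Nb/2+1)-th order statistics)
gives the EC estimator, which is robust when the bootstrap-draw
distribution is skewed — the median's breakdown point is 1/2 versus 0
for the mean. Incalculable or negative correction terms are substituted
by 0, terms above 1 are capped, and estimates are clamped into [0, 1].

The package also ships the mixture-cure Monte-Carlo harness (exponential
latency, administrative censoring at 3000 days, scenarios A/B/C with
λ = 0.0013 / 0.0005 / 0.0033 per day) reporting mean estimate, bias, SD
and MSE per estimator, plus bootstrap diagnostics (skewness, draw
export) and a Kaplan–Meier tail profile for judging follow-up adequacy.

## Worked example: the Mayo PBC trial

The D-penicillamine trial in primary biliary cirrhosis: 312 randomized
participants, 125 deaths over roughly ten years of follow-up, arms
pooled, endpoint time to death.

```r
library(cureboot)
pbc <- load_pbc()                      # survival::pbc, randomized cohort
estimate_cure_rate(pbc, "km")
#> KM cure-rate estimate: 0.3406
est <- estimate_cure_rate(pbc, "ec", seed = 1)
est
#> EC cure-rate estimate: 0.2938
#>   y* = 0.86, bootstrap aggregate g = 0.2803 (200 draws, 204 attempts)
estimate_cure_rate(pbc, "ek", seed = 1)
#> EK cure-rate estimate: 0.2150
#>   y* = 0.88, bootstrap aggregate g = 0.2344 (200 draws, 204 attempts)
skewness(est$draws$values)
#> [1] -0.652
```

Read: the raw plateau says 34% of patients are cured, but the curve is
still falling near the end of follow-up, so that is an overestimate. The
bootstrap-draw distribution is left-skewed (skewness −0.65), which drags
the mean-based correction down to 21.5%; the median-based correction,
insensitive to the skewed tail of the draws, lands at 29.4%. The tail
profile that motivates the correction:

```r
round(km_profile(pbc), 4)
#>      y   surv
#> 1 0.60 0.5969
#> ...
#> 5 0.92 0.3406
#> 9 1.00 0.3406
```

`export_diagnostics(est, "pbc_ec")` writes the draws and a JSON summary
(mean, median, |mean − median|, skewness, y*) for histogramming.

A thin command-line front end over the same functions is installed at
`inst/cli/cureboot.R` (subcommands `estimate`, `simulate`, `profile`).

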