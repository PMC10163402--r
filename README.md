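# stepdyn

Person-specific dynamical modeling of step-count responses to motivational
messages.

## The problem

Digital messaging interventions nudge people to move more by pushing short
motivational notifications to their phones while a wrist-worn tracker
records minute-level step counts. Whether a message "works" — and for whom,
and how fast — is a question about *dynamics*: the transient change in
stepping in the minutes and hours after a message lands, relative to what
that person would have done anyway. Group-mean contrasts wash these
transients out; person-specific system identification keeps them.

`stepdyn` implements that analysis end to end for studies with the
following shape: participants wear a tracker for months, declare a daily
availability window of at least 10 hours, and receive 0–6 messages per day
at random times (never closer than 15 minutes apart) drawn from three
content libraries — affectively framed (54 messages), social-cognitively
framed (54), and inspirational quotes (27). Because raw data from such
trials are rarely public, the package ships a synthetic cohort generator
that emulates the whole protocol from known ground-truth dynamics, so every
stage of the pipeline is testable and the group-level machinery can be
exercised on realistic cohorts.

## The model

For each participant and day type (weekday vs weekend — a *switched*
system), step counts summed into 15-minute epochs `y(k)` are modeled as an
order-5 ARX (autoregressive with exogenous inputs) process:

```
y(k) = a0 + Σ_{i=1..5} a_i y(k−i) + Σ_{j=1..3} Σ_{i=0..5} b_ji u_j(k−i) + ε(k)
```

where `u_j(k) ∈ {0,1}` flags delivery of a message from library `j` in
epoch `k`. The 24 coefficients are estimated by least squares over all
eligible epochs (days are treated as independent; lags never cross
midnight). Each fitted model is then *probed*: a unit impulse on one
message channel is simulated forward 40 epochs (600 min), giving the
impulse response (expected step change per epoch) and its running sum, the
cumulative step response. Seven control-systems features summarise each
curve — initial delay, peak magnitude, peak delay, steady state, rise time
(10%→90% of steady state), settling time (enters ±5% of steady state), and
effective time (duration the bootstrap error band excludes zero). Feature
grids across participants feed two-way repeated-measures ANOVAs
(message × day, Greenhouse–Geisser corrected, generalized η²), Friedman
tests with Kendall W for non-normal features, and Bonferroni pairwise post
hocs.

## Worked example

```r
library(stepdyn)
set.seed(1)

specs  <- paper_like_specs(8, noise_sd = 25)       # ground-truth participants
cfg    <- simulation_config(n_participants = 8, n_days = 56, seed = 1)
models <- list()
for (s in specs)
  models[[s$participant_id]] <-
    fit_switched_models(simulate_participant_series(s, cfg))

print(models$P001$weekday)
#> ARX model: 2440 rows, rank 24, RMSE 24.6
#> ARX coefficients (order 5, d = 15 min)
#>   a0: 74.27
#>   a:   0.469793 -0.026025  0.015944 -0.010860  0.008387
#>   spectral radius: 0.5176
```

The fitted output lag (0.47) and intercept recover this participant's
ground truth (pole 0.48, a0 69.8) from 8 weeks of noisy epochs. Probing the
affective channel with bootstrap error bounds:

```r
curve <- estimate_error_bounds(models$P001$weekday, "affective", B = 500)
extract_features(curve)
#>  initial_delay peak_magnitude     peak_delay   steady_state      rise_time
#>          0.000         56.486         75.000        215.735         90.000
#>  settling_time effective_time
#>        105.000        600.000
```

One affective message is expected to add ~216 steps in total for this
participant on weekdays; the effect peaks at 56 steps/epoch 75 minutes
after receipt, climbs from 10% to 90% of its total in 90 minutes, and is
distinguishable from model noise over the whole 600-minute horizon. Group
statistics and the heterogeneity summary:

```r
ft <- feature_table(models, B = 0)   # skip bands: grid features only
rm_anova_2way(ft, "rise_time")
#> repeated-measures ANOVA for rise_time (n = 8)
#>         effect     F   df1   df2      p    ges corrected
#> 1:     message 0.538     2    14 0.5960 0.0233     FALSE
#> 2:         day 4.941     1     7 0.0616 0.1400     FALSE
#> 3: interaction 0.640     2    14 0.5420 0.0260     FALSE

best_message_summary(ft)
#>    day_type     message_type n_best total fraction
#> 1:  weekday        affective      3     8    0.375
#> 2:  weekday            quote      3     8    0.375
#> 3:  weekday social_cognitive      2     8    0.250
#> ...
```

At n = 8 the built-in weekend/weekday difference in rise time is visible
but not yet significant (p = .06); at the protocol's full n = 45 it is (see
`tests/testthat/test-acceptance.R`). No message type is best for everyone —
the motivation for person-specific modeling.

The same pipeline runs from files:

```sh
Rscript inst/cli/stepdyn.R simulate   --out raw/ --seed 3 --participants 5 --days 28
Rscript inst/cli/stepdyn.R validate   --in raw/
Rscript inst/cli/stepdyn.R preprocess --in raw/ --out epochs/
Rscript inst/cli/stepdyn.R run        --config cfg.yaml
```

or in R via `run_pipeline(pipeline_config(...))`, which writes per-stage
artifacts plus an MD5 manifest (byte-identical on reruns with the same
seed).

## Layout

| path | contents |
|---|---|
| `R/synthetic_cohort.R` | protocol-faithful cohort generator (schedules, ARX simulation, minute emission, missingness) |
| `R/preprocessing.R` | stream merging, missing-minute classification, ≤3-min interpolation, 15-min epoch aggregation, day-type split |
| `R/system_identification.R` | design construction, QR least squares, switched weekday/weekend fits |
| `R/response_analysis.R` | impulse/cumulative response simulation, parametric-bootstrap bounds, the 7 features |
| `R/feature_statistics.R` | descriptives, normality gate, RM-ANOVA + GG, Friedman + Kendall W, post hocs, heterogeneity |
| `R/pipeline.R` | config, orchestration, validation, manifests |
| `vignettes/stepdyn-methods.Rmd` | modeling assumptions, parameter choices, limitations |
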