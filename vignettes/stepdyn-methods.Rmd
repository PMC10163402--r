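---
title: "Methods: person-specific ARX modeling of message-driven step dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: person-specific ARX modeling of message-driven step dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepdyn)
```

# The model and its assumptions

`stepdyn` treats a person's 15-minute epoch step counts on one day type as
the output of a linear time-invariant system driven by message deliveries:

$$y(k) = a_0 + \sum_{i=1}^{5} a_i\,y(k-i)
  + \sum_{j=1}^{3}\sum_{i=0}^{5} b_{ji}\,u_j(k-i) + \varepsilon(k)$$

with binary inputs $u_j$ for the affective, social-cognitive and
inspirational-quote message channels. The assumptions worth being explicit
about:

* **Linearity and superposition.** Message effects add; two messages in
  quick succession produce the sum of their individual responses. The
  protocol's 15-minute minimum spacing and low daily dose (0–6) keep this
  mild.
* **Switched stationarity.** Dynamics are constant within a day type but
  may differ between weekdays and weekends; a separate model is fitted for
  each (a *switched system*). No drift across the study is modeled.
* **Day independence.** Lagged regressors never cross midnight; each day's
  recursion starts from rest. Overnight carry-over of message effects is
  assumed negligible.
* **Exogenous inputs.** Delivery times are randomized by design, so the
  inputs are independent of the noise — the condition under which least
  squares is consistent here.

Order 5 (75 minutes of memory, plus the current epoch of input) is the
package default, fixed as a configuration constant rather than selected
per participant; the constant lives in one place (`order` arguments) for
sensitivity analyses. With the intercept this gives
$1 + 5 + 3\times 6 = 24$ free coefficients.

## Estimation

Coefficients minimise the residual sum of squares over all *eligible*
rows: target epoch valid, all five preceding epochs valid, same day. The
solution uses a QR factorisation, never an explicit normal-equations
inverse; the (unit-weight) covariance is
$\hat\sigma^2 (X^\top X)^{-1}$ with
$\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank})$. A message type never
delivered on a day type makes the design rank deficient; the offending
columns are dropped, their coefficients reported as zero, and the model
flagged `rank_deficient` — plain least squares is kept as the estimator,
with an optional ridge penalty (`ridge > 0`) available for stress cases
only.

## Response curves and the seven features

Each fitted model is probed with a unit impulse on one channel at epoch 0.
Because the response is defined as the deviation from the no-message
trajectory, the intercept cancels and the recursion runs on the $a$ and
$b$ coefficients alone for 40 epochs (600 minutes — the horizon at which
observed effective times top out, and past which a stable model's
responses are numerically settled).

* From the impulse curve: **peak magnitude** $\max_k |h(k)|$ (absolute
  value, since momentary peaks are positive even when cumulative totals
  are negative), **peak delay** (earliest maximiser on ties), **initial
  delay** (first epoch whose impulse error band excludes zero; reported
  as 0 when no epoch does, matching the empirical observation that lag-0
  coefficients dominate).
* From the cumulative curve $c(k)=\sum_{i\le k} h(i)$: **steady state**
  $c(40)$; **rise time** and **settling time** computed on the *ratio*
  $c(k)/c(40)$ so that negative steady states are handled symmetrically
  (rise: first ratio $\ge 0.9$ minus first ratio $\ge 0.1$; settling:
  earliest epoch after which the ratio stays inside $[0.95, 1.05]$);
  **effective time**, the total time the cumulative band excludes zero.
  A steady state of exactly zero leaves the ratio features undefined; the
  feature set is flagged and those entries are `NA`.

Two of these definitions were genuinely open design choices: the error
bands are a **parametric bootstrap** of the coefficient sampling
distribution ($B = 500$ draws from $N(\hat\beta, \widehat{\mathrm{cov}})$,
pointwise 2.5/97.5 percentiles) — chosen over delta-method recursion for
simplicity and over residual resampling for speed, with the covariance
eigen-clipped to PSD if column dropping dented it; and **effective time is
computed on the cumulative curve** (the impulse-based variant is a
one-line change in `extract_features` if wanted). Both are flagged here
because other implementations could reasonably differ.

# The synthetic cohort: a stated world

The generator emulates the messaging protocol exactly as specified:

* availability windows of **at least 10 hours** (presets draw starts in
  07:00–09:00 and lengths of 10–14 h);
* **0–6 messages/day**, count drawn *uniformly* — the protocol says only
  "at random each night", so uniform is the minimal assumption, kept
  configurable;
* delivery minutes uniform in the window under the **15-minute spacing**
  constraint (rejection sampling with a shifted-uniform fallback);
* message type by uniform draw over the **pooled 135-message library**
  (54/54/27), not uniform over libraries — this reproduces the observed
  40/39/20 delivery split, which matches pooled-uniform expectation;
* minute-level emission: latent epoch sums from the ground-truth ARX
  recursion (noise SD 25 steps/epoch by default), floored at zero and
  rounded *only* when minutes are emitted (the latent series is kept for
  recovery oracles), then split across each epoch's 15 minutes by a
  symmetric multinomial draw so re-aggregation is exact;
* missingness from two mechanisms: per-minute heart-rate dropout
  (default 5%) and nonwear blocks (default 3/week, lengths a mixture of
  1–3-minute and geometric 4+-minute runs) so both the interpolation and
  the exclusion paths of preprocessing are exercised.

The `paper_like_specs()` presets encode the heterogeneity the analysis is
meant to expose: per-participant first-order-like dynamics embedded in the
order-5 parameterisation, weekday poles 0.30–0.50 vs weekend 0.55–0.75
(slower weekend dynamics → longer rise/settling times), weekday lag-0
input gains 15–55 vs weekend 25–75 steps (larger weekend peaks), and
per-message-type steady-state targets drawn i.i.d. from
$N(50, 150^2)$ (weekday) or $N(50, 250^2)$ (weekend) truncated to
$[-300, 800]$ — so cumulative responses span negative to ~800 steps, *no
message type is systematically better*, and day type affects speed and
peak but not mean steady state. Later input lags are set from the
steady-state target, which allows positive momentary peaks with negative
totals, a pattern present in real cohorts.

What the generator does **not** emulate: circadian within-day activity
structure, weather and context, behavior change across the study, device
step-detection error, or message content/imagery. A green end-to-end test
therefore establishes that the pipeline recovers *its own* generative
world — protocol constraints, ARX dynamics, missingness handling — not
that the ARX family is an adequate description of any particular human.

## Calendar conventions

Day 1 of a simulated study is a Monday (2019-04-15 by default); weekend
means Saturday/Sunday by ISO weekday number, evaluated per calendar date.
Day boundaries are local midnight, and the ±2-hour window extension is
clipped there because days are independent.

# Preprocessing rules

A minute is *missing* iff it recorded zero steps while heart rate was
absent (zero steps with heart rate present is a genuine observation).
Maximal missing runs of ≤3 minutes with observed flanks are filled by
linear interpolation between the flanking step counts; longer runs, and
runs touching the record edge (no flank to interpolate from), are
excluded. Epochs are anchored at clock quarter-hours (:00/:15/:30/:45) —
the anchor is a reproducibility choice, keeping epochs aligned across days
— and an epoch is valid only if fully covered by non-excluded minutes.
Message indicators are capped at 1 per library per epoch (the 15-minute
spacing makes a doubled indicator nearly impossible, but the cap makes the
contract total). Undelivered messages are dropped before any modeling.

# Statistics

Features pass a per-cell Shapiro–Wilk gate (α = .05, any failing or
degenerate cell flags the feature). Normal features get a two-way
repeated-measures ANOVA with within-person message (2 df) and day (1 df)
factors, each effect tested against its subject-by-effect stratum.
Sphericity of the message and interaction effects is checked with
Mauchly's test; on rejection the Greenhouse–Geisser ε multiplies both
degrees of freedom (the origin of fractional dfs), with an
`gg = "always"` option. Effect size is **generalized** η² — effect SS over
effect SS plus *all* subject-level error SS — which is smaller than
partial η²; the choice is stated prominently because the two are often
conflated. Non-normal features get Friedman tests on within-participant
ranks of the three message types, separately per day type, with the
midrank tie correction and Kendall
$W = \chi^2 / (n(k-1))$; fully tied data yield $\chi^2 = 0, W = 0$ by
convention. Significant main effects trigger Bonferroni-corrected paired
t tests (Wilcoxon signed-rank on the nonparametric route); zero-variance
differences are reported as undefined rather than tested.

The repeated-measures machinery is implemented from sums of squares in
this package (not delegated), and is verified in the test suite against
`aov()` error strata, a brute-force cell-means oracle, and frozen
reference values computed once with an independent implementation for the
Mauchly/Greenhouse–Geisser path.

# Numerical and degenerate-input choices

* Ties at the impulse peak break toward the earliest epoch.
* Bootstrap percentile bands are clamped to bracket the point estimate
  (pointwise percentiles of a finite sample need not).
* `sigma2` uses the $n - \mathrm{rank}$ denominator (unbiased under the
  model).
* Unstable fitted dynamics (spectral radius ≥ 1) are simulated to the
  horizon anyway and flagged, never truncated silently.
* All seeds flow from a single integer; cohort generation, bootstrap and
  pipeline stages are bit-reproducible (manifest checksums are compared
  in the tests).

# Runtime scaling in the test suite

The acceptance-level tests use the protocol's stated sizes (10,000
scheduler days; 50 participants × 26 weeks for coefficient recovery;
1,000 null replicates for ANOVA calibration; 45 participants × 26 weeks
for the qualitative-pattern cohort). To keep the full suite within a few
minutes on one CPU, the two cohort-scale tests simulate at the *epoch*
level via `simulate_participant_series()` — the generator's latent layer —
rather than writing and re-reading minute-level files; the minute layer
(emission, missingness, interpolation, re-aggregation) is covered by its
own round-trip oracle, which proves the two routes coincide when
missingness is off. Feature extraction in the cohort test skips bootstrap
bands (`B = 0`) since only grid features enter those ANOVAs.

# Known limitations

* The ARX family is linear; saturation (a ceiling on how much stepping a
  message can add) and interaction between messages are not represented.
* Listwise deletion for incomplete feature grids; no imputation.
* The normality gate is per-cell Shapiro–Wilk at a fixed α — a convention,
  not an inference.
* The daily message count distribution and the randomizer's exact scheme
  are assumptions (uniform), configurable but unverifiable from protocol
  text alone.
* The command-line front end ships as an `Rscript` entry point under
  `inst/cli/`; R packages do not install standalone executables, so
  `stepdyn <cmd>` is spelled `Rscript inst/cli/stepdyn.R <cmd>`.
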