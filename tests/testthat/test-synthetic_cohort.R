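test_that("message schedules respect the protocol constraints", {
  spec <- toy_spec()
  cfg <- simulation_config(n_participants = 1, n_days = 1, seed = 1)
  set.seed(11)
  n_days <- 2000L
  counts <- integer(n_days)
  min_gap <- Inf
  for (d in seq_len(n_days)) {
    s <- generate_message_schedule(d, spec, cfg)
    counts[d] <- nrow(s)
    if (nrow(s)) {
      expect_true(all(s$minute >= spec$window_start &
                        s$minute < spec$window_end))
      if (nrow(s) > 1L) min_gap <- min(min_gap, diff(s$minute))
    }
  }
  expect_lte(max(counts), 6L)
  expect_gte(min_gap, 15)
  # uniform daily count on 0..6
  expect_setequal(sort(unique(counts)), 0:6)

  # forced quiet day
  expect_identical(nrow(generate_message_schedule(1, spec, cfg,
                                                  n_messages = 0L)), 0L)
})

test_that("library draws follow pooled 54:54:27 proportions", {
  spec <- toy_spec()
  cfg <- simulation_config(seed = 1)
  set.seed(5)
  libs <- unlist(lapply(1:4000, function(d)
    generate_message_schedule(d, spec, cfg)$library))
  pr <- prop.table(table(factor(libs, c("affective", "social_cognitive",
                                        "quote"))))
  # binomial tolerance at ~12k draws
  expect_equal(unname(pr[["affective"]]), 0.4, tolerance = 0.05)
  expect_equal(unname(pr[["quote"]]), 0.2, tolerance = 0.06)
})

test_that("delivery failures are flagged at the configured rate", {
  spec <- toy_spec()
  cfg <- simulation_config(seed = 1, delivery_failure_prob = 0.3)
  set.seed(3)
  del <- unlist(lapply(1:3000, function(d)
    generate_message_schedule(d, spec, cfg)$delivered))
  expect_equal(mean(!del), 0.3, tolerance = 0.05)
})

test_that("participant_spec rejects protocol violations", {
  co <- first_order_coeffs()
  expect_error(participant_spec("X", co, co, window_start = 480,
                                window_end = 1000),
               "600 minutes")
  expect_error(participant_spec("X", co, co, noise_sd = -1), "noise_sd")
  unstable <- arx_coefficients(a = c(1.2, 0, 0, 0, 0))
  expect_error(participant_spec("X", unstable, co), "unstable")
  expect_s3_class(participant_spec("X", unstable, co,
                                   allow_unstable = TRUE),
                  "participant_spec")
})

test_that("ARX epoch recursion matches hand computation", {
  co <- first_order_coeffs(pole = 0.5, gain = 10)
  u <- matrix(0L, 6, 3)
  u[1, 1] <- 1L
  y <- simulate_epoch_series(co, u, noise_sd = 0)
  expect_equal(y, 10 * 0.5^(0:5))

  # zero system stays at rest
  expect_equal(simulate_epoch_series(arx_coefficients(),
                                     matrix(0L, 8, 3), 0),
               rep(0, 8))

  # intercept-only system converges to a0 / (1 - a1)
  co2 <- arx_coefficients(a0 = 30, a = c(0.4, 0, 0, 0, 0))
  y2 <- simulate_epoch_series(co2, matrix(0L, 60, 3), 0)
  expect_equal(y2[60], 30 / 0.6, tolerance = 1e-9)

  # general order-5 case against a literal translation of the recursion
  set.seed(21)
  co3 <- arx_coefficients(a0 = 5, a = c(0.3, 0.1, -0.05, 0.02, 0.01),
                          b = matrix(rnorm(18, 0, 4), 3, 6))
  u3 <- matrix(rbinom(45, 1, 0.2), 15, 3)
  got <- simulate_epoch_series(co3, u3, 0)
  ref <- numeric(15)
  for (k in 1:15) {
    acc <- co3$a0
    for (i in 1:5) if (k - i >= 1) acc <- acc + co3$a[i] * ref[k - i]
    for (j in 1:3) for (i in 0:5) if (k - i >= 1)
      acc <- acc + co3$b[j, i + 1] * u3[k - i, j]
    ref[k] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-12)

  expect_error(simulate_epoch_series(co, u, noise_sd = -2), "noise_sd")
  set.seed(9); y_a <- simulate_epoch_series(co, u, 5)
  set.seed(9); y_b <- simulate_epoch_series(co, u, 5)
  expect_identical(y_a, y_b)
})

test_that("distribute_to_minutes round-trips epoch totals", {
  expect_identical(distribute_to_minutes(0), rep(0L, 15))
  set.seed(2)
  m <- distribute_to_minutes(150)
  expect_length(m, 15)
  expect_true(all(m >= 0L))
  expect_identical(sum(m), 150L)

  # property: re-aggregation recovers rounded/floored totals
  for (rep in 1:20) {
    x <- round(runif(12, -5, 400))
    mm <- distribute_to_minutes(x)
    agg <- colSums(matrix(mm, 15))
    expect_equal(agg, pmax(0, x))
  }
})

test_that("missingness injection behaves at the extremes", {
  dt <- flat_day_minutes(480, 1200, steps = 4)
  spec0 <- toy_spec(hr_dropout = 0, nonwear = 0)
  set.seed(1)
  expect_equal(inject_missingness(dt, spec0), dt)

  spec1 <- toy_spec(hr_dropout = 0.2, nonwear = 0)
  set.seed(4)
  out <- inject_missingness(dt, spec1)
  expect_lt(abs(mean(out$hr_present == 0L) - 0.2), 0.03)
  expect_identical(out$steps, dt$steps)  # dropout alone leaves steps intact

  # forced nonwear blocks null out steps and heart rate
  spec2 <- toy_spec(hr_dropout = 0, nonwear = 70)  # ~10 blocks/day
  set.seed(6)
  out2 <- inject_missingness(dt, spec2)
  gone <- out2$steps == 0 & out2$hr_present == 0L
  expect_gt(sum(gone), 0)
  r <- rle(gone)
  expect_true(any(r$lengths[r$values] >= 1))
})

test_that("generate_cohort is byte-deterministic and calendar-correct", {
  cfg <- simulation_config(n_participants = 2, n_days = 7, seed = 42)
  specs <- list(toy_spec("A1"), toy_spec("A2"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, specs, d1, keep_latent = TRUE)
  generate_cohort(cfg, specs, d2, keep_latent = TRUE)
  for (f in list.files(d1)) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]], label = f)
  }
  expect_length(list.files(d1, pattern = "_minutes\\.csv$"), 2L)

  # start date 2019-04-15 is a Monday; days 6 and 7 are the weekend
  b <- read_participant_bundle(d1, "A1")
  series <- preprocess_participant(b$minutes, b$messages, b$window, "A1")
  types <- vapply(series, `[[`, "", "day_type")
  expect_identical(types, c(rep("weekday", 5), "weekend", "weekend"))

  # ground-truth JSON faithfully stores the coefficients
  tr <- stepdyn:::read_truth(file.path(d1, "A1_truth.json"))
  expect_equal(tr$weekday$a, specs[[1]]$weekday_coeffs$a)
  expect_equal(tr$weekend$b, specs[[1]]$weekend_coeffs$b)
})

test_that("paper_like_specs span the study's heterogeneity", {
  set.seed(10)
  specs <- paper_like_specs(60)
  # every window honours the 10-hour protocol floor
  lens <- vapply(specs, function(s) s$window_end - s$window_start, 0)
  expect_true(all(lens >= 600))
  # all ground truths stable
  sr <- vapply(specs, function(s)
    max(arx_spectral_radius(s$weekday_coeffs),
        arx_spectral_radius(s$weekend_coeffs)), 0)
  expect_true(all(sr < 1))
  # implied steady states take both signs and reach several hundred steps
  ss <- unlist(lapply(specs, function(s) vapply(1:3, function(j) {
    co <- s$weekend_coeffs
    sum(co$b[j, ]) / (1 - sum(co$a))
  }, 0)))
  expect_lt(min(ss), 0)
  expect_gt(max(ss), 500)
})
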