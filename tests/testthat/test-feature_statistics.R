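test_that("descriptives match a streaming oracle", {
  set.seed(61)
  ft <- make_feature_table(n = 8, feature_name = "steady_state", sd = 40)
  d <- describe_features(ft)
  expect_identical(nrow(d), 6L)
  # independent two-pass oracle on one cell
  cell <- ft[message_type == "quote" & day_type == "weekend"]$value
  row <- d[message_type == "quote" & day_type == "weekend"]
  expect_equal(row$mean, sum(cell) / length(cell))
  expect_equal(row$sd, sqrt(sum((cell - mean(cell))^2) / (length(cell) - 1)))
  expect_equal(c(row$min, row$max), range(cell))

  # single observation: SD undefined
  one <- ft[participant == "S01"]
  expect_true(all(is.na(describe_features(one)$sd)))

  # constant feature: SD 0, zero-length range
  cst <- data.table::copy(ft)[, value := 7]
  dc <- describe_features(cst)
  expect_true(all(dc$sd == 0))
  expect_true(all(dc$max - dc$min == 0))

  expect_error(describe_features(ft[0]), "empty")
})

test_that("normality gate flags boundary point masses and constants", {
  set.seed(62)
  ok <- make_feature_table(n = 45, feature_name = "steady_state", sd = 30)
  expect_true(check_normality(ok, "steady_state")$normal)

  # point mass at a boundary (like effective time stuck at 15)
  mass <- data.table::copy(ok)
  mass[value < 60, value := 15]
  expect_false(check_normality(mass, "steady_state")$normal)

  cst <- data.table::copy(ok)[, value := 3]
  expect_false(check_normality(cst, "steady_state")$normal)
})

test_that("rm ANOVA sums of squares match a brute-force oracle (5 subjects)",
{
  set.seed(63)
  ft <- make_feature_table(n = 5, feature_name = "x", day_shift = 12,
                           sd = 6)
  res <- rm_anova_2way(ft, "x", gg = "never")
  # brute-force cell-mean decomposition, written independently
  Y <- array(NA_real_, c(5, 3, 2))
  for (r in seq_len(nrow(ft))) {
    s <- match(ft$participant[r], sprintf("S%02d", 1:5))
    m <- match(ft$message_type[r],
               c("affective", "social_cognitive", "quote"))
    d <- match(ft$day_type[r], c("weekday", "weekend"))
    Y[s, m, d] <- ft$value[r]
  }
  gm <- mean(Y)
  ss <- function(x) sum(x^2)
  ss_m <- 0; ss_d <- 0; ss_md <- 0; ss_s <- 0
  for (m in 1:3) ss_m <- ss_m + 5 * 2 * (mean(Y[, m, ]) - gm)^2
  for (d in 1:2) ss_d <- ss_d + 5 * 3 * (mean(Y[, , d]) - gm)^2
  for (s in 1:5) ss_s <- ss_s + 6 * (mean(Y[s, , ]) - gm)^2
  for (m in 1:3) for (d in 1:2)
    ss_md <- ss_md + 5 * (mean(Y[, m, d]) - mean(Y[, m, ]) -
                            mean(Y[, , d]) + gm)^2
  expect_equal(res$ss$message, ss_m)
  expect_equal(res$ss$day, ss_d)
  expect_equal(res$ss$interaction, ss_md)
  expect_equal(res$ss$subject, ss_s)
  # strata add up to the total
  expect_equal(Reduce(`+`, res$ss[c("subject", "message", "day",
                                    "interaction", "err_message",
                                    "err_day", "err_interaction")]),
               res$ss$total)
  # and the full table agrees with base R's aov decomposition
  av <- summary(stats::aov(value ~ message_type * day_type +
                             Error(participant / (message_type * day_type)),
                           data = as.data.frame(ft)))
  f_aov <- c(av[["Error: participant:message_type"]][[1]]$`F value`[1],
             av[["Error: participant:day_type"]][[1]]$`F value`[1],
             av[["Error: participant:message_type:day_type"]][[1]]$`F value`[1])
  expect_equal(res$effects$F, unname(f_aov), tolerance = 1e-10)
})

test_that("constructed day effect is detected; message effect stays null", {
  set.seed(64)
  ft <- make_feature_table(n = 20, feature_name = "x", day_shift = 25,
                           sd = 4)
  res <- rm_anova_2way(ft, "x")
  eff <- res$effects
  expect_lt(eff[eff$effect == "day"]$p, 1e-6)
  expect_gt(eff[eff$effect == "message"]$p, 0.01)
  expect_gt(eff[eff$effect == "day"]$ges, eff[eff$effect == "message"]$ges)
  expect_true(all(eff$ges >= 0 & eff$ges <= 1))
  expect_true(all(eff$F >= 0))
})

test_that("Greenhouse-Geisser machinery matches the frozen oracle values", {
  # expected values computed once with an independent reference
  # implementation (pingouin 0.6.1: rm_anova, sphericity, epsilon) on the
  # deterministic fixture; frozen here
  ft <- gg_fixture()
  res <- rm_anova_2way(ft, "x", gg = "always")
  sph <- res$sphericity$message
  expect_equal(sph$W, 0.3389171922, tolerance = 1e-8)
  expect_equal(sph$p, 0.0044716520, tolerance = 1e-7)
  expect_equal(sph$eps, 0.6020169466, tolerance = 1e-8)
  expect_equal(res$sphericity$interaction$eps, 0.9851178478,
               tolerance = 1e-8)
  eff <- res$effects
  msg <- eff[eff$effect == "message"]
  expect_equal(msg$F, 1.89441103, tolerance = 1e-7)
  expect_equal(msg$p, 0.1927847269, tolerance = 1e-7)  # GG-corrected
  expect_equal(msg$df1, 2 * 0.6020169466, tolerance = 1e-7)
  expect_equal(msg$ges, 0.0921844119, tolerance = 1e-8)
  day <- eff[eff$effect == "day"]
  expect_equal(day$F, 72.80293032, tolerance = 1e-7)
  expect_equal(day$ges, 0.0141327329, tolerance = 1e-8)
  # with the Mauchly gate, the violating message factor is corrected but
  # the near-spherical interaction is not
  res2 <- rm_anova_2way(ft, "x", gg = "mauchly")
  eff2 <- res2$effects
  expect_true(eff2[eff2$effect == "message"]$corrected)
  expect_false(eff2[eff2$effect == "interaction"]$corrected)
})

test_that("Friedman statistic matches hand computation and stats oracle", {
  # 4 blocks, one treatment always top, fixed order -> chi2 = 8, W = 1
  ft <- data.table::data.table(
    participant = rep(sprintf("S%d", 1:4), each = 3),
    message_type = rep(c("affective", "social_cognitive", "quote"), 4),
    day_type = "weekday", feature = "x",
    value = rep(c(3, 2, 1), 4))
  fr <- friedman_by_daytype(ft, "x", "weekday")
  expect_equal(fr$chi2, 8)
  expect_equal(fr$kendall_w, 1)
  expect_identical(fr$df, 2L)

  # identical values across treatments: full ties -> 0 by convention
  tie <- data.table::copy(ft)[, value := 5]
  fr0 <- friedman_by_daytype(tie, "x", "weekday")
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$kendall_w, 0)

  # random data (with duplicates forcing midranks) agrees with
  # stats::friedman.test
  set.seed(65)
  ftr <- make_feature_table(n = 9, feature_name = "x", sd = 3)
  ftr[, value := round(value)]
  fr2 <- friedman_by_daytype(ftr, "x", "weekend")
  wide <- data.table::dcast(ftr[day_type == "weekend"],
                            participant ~ message_type,
                            value.var = "value")
  ref <- stats::friedman.test(as.matrix(wide[, -1]))
  expect_equal(fr2$chi2, unname(ref$statistic))
  expect_equal(fr2$p, ref$p.value)
  expect_true(fr2$kendall_w >= 0 && fr2$kendall_w <= 1)

  expect_error(friedman_by_daytype(ft[participant == "S1"], "x", "weekday"),
               "at least 2")
})

test_that("label permutation leaves the Friedman null distribution invariant",
{
  # at n = 3 blocks the statistic's distribution over all label
  # permutations within blocks must be identical for any relabeling
  base <- matrix(c(1.2, 0.4, 2.2,
                   0.7, 1.9, 0.1,
                   2.5, 0.3, 1.1), 3, byrow = TRUE)
  stat_of <- function(m) {
    ft <- data.table::data.table(
      participant = rep(sprintf("S%d", 1:3), each = 3),
      message_type = rep(c("affective", "social_cognitive", "quote"), 3),
      day_type = "weekday", feature = "x", value = as.vector(t(m)))
    friedman_by_daytype(ft, "x", "weekday")$chi2
  }
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  dists <- lapply(perms, function(pp) {
    # enumerate all within-block permutations of the relabeled matrix
    m0 <- base[, pp]
    all_p <- expand.grid(rep(list(1:6), 3))
    p6 <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
               c(3, 2, 1))
    sort(apply(all_p, 1, function(ix) {
      m <- rbind(m0[1, p6[[ix[1]]]], m0[2, p6[[ix[2]]]], m0[3, p6[[ix[3]]]])
      stat_of(m)
    }))
  })
  for (k in 2:4) expect_equal(dists[[k]], dists[[1]])
})

test_that("pairwise post hocs apply the Bonferroni factor", {
  set.seed(66)
  ft <- make_feature_table(n = 10, feature_name = "x",
                           message_shift = c(20, 0, 0), sd = 3)
  ph <- pairwise_posthoc(ft, "x", "message")
  expect_identical(nrow(ph), 3L)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  aff <- ph[(level_a == "affective" | level_b == "affective")]
  expect_true(all(aff$p_adj < 0.01))

  # agreement with a textbook paired-t computation on 6 pairs
  x <- c(10, 12, 9, 14, 11, 13); y <- c(8, 11, 9, 10, 12, 9)
  ft2 <- data.table::data.table(
    participant = rep(sprintf("S%d", 1:6), 2),
    message_type = "affective",
    day_type = rep(c("weekday", "weekend"), each = 6),
    feature = "x", value = c(x, y))
  ph2 <- pairwise_posthoc(ft2, "x", "day")
  d <- x - y
  t_ref <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(abs(ph2$statistic), abs(t_ref))
  expect_equal(ph2$p_raw, 2 * stats::pt(-abs(t_ref), 5))

  # identical paired samples: t = 0, adjusted p = 1
  ft3 <- data.table::copy(ft2)[day_type == "weekend",
                               value := ft2[day_type == "weekday"]$value]
  ph3 <- pairwise_posthoc(ft3, "x", "day")
  expect_equal(ph3$statistic, 0)
  expect_equal(ph3$p_adj, 1)

  # Wilcoxon route works
  ph4 <- pairwise_posthoc(ft, "x", "message", parametric = FALSE)
  expect_identical(nrow(ph4), 3L)
  expect_true(all(ph4$p_adj <= 1))
})

test_that("best-message summary partitions participants exhaustively", {
  set.seed(67)
  ft <- make_feature_table(n = 30, feature_name = "steady_state", sd = 50)
  het <- best_message_summary(ft)
  for (dtp in c("weekday", "weekend"))
    expect_identical(sum(het[day_type == dtp]$n_best), 30L)
  expect_true(all(het$fraction >= 0 & het$fraction <= 1))
  expect_equal(sum(het$fraction), 2)
})
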