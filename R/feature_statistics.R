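#' Descriptive statistics per feature, message type and day type
#'
#' @param table long-format feature table (`participant`, `message_type`,
#'   `day_type`, `feature`, `value`).
#' @param features optional subset of feature names.
#' @return `data.table` with mean, SD (NA for a single observation), min,
#'   max and n per feature x message x day cell.
#' @export
describe_features <- function(table, features = NULL) {
  tbl <- as.data.table(table)
  if (!nrow(tbl)) stop("empty feature table")
  if (!is.null(features)) tbl <- tbl[feature %in% features]
  out <- tbl[!is.na(value),
             .(mean = mean(value),
               sd = if (.N > 1L) sd(value) else NA_real_,
               min = min(value), max = max(value), n = .N),
             by = .(feature, message_type, day_type)]
  setorder(out, feature, day_type, message_type)
  out[]
}

# complete-case wide array Y[subject, message, day] for one feature
feature_array <- function(table, feature_name) {
  tbl <- as.data.table(table)[feature == feature_name & !is.na(value)]
  wide <- data.table::dcast(tbl, participant ~ message_type + day_type,
                            value.var = "value")
  needed <- as.vector(outer(MESSAGE_TYPES, c("weekday", "weekend"),
                            paste, sep = "_"))
  missing_cols <- setdiff(needed, names(wide))
  if (length(missing_cols)) wide[, (missing_cols) := NA_real_]
  wide <- wide[complete.cases(wide[, ..needed])]
  n <- nrow(wide)
  arr <- array(NA_real_, c(n, 3L, 2L),
               dimnames = list(wide$participant, MESSAGE_TYPES,
                               c("weekday", "weekend")))
  for (m in 1:3) for (d in 1:2)
    arr[, m, d] <- wide[[paste(MESSAGE_TYPES[m],
                               c("weekday", "weekend")[d], sep = "_")]]
  arr
}

#' Per-cell normality check for a feature
#'
#' Applies a Shapiro-Wilk test in each message x day cell; the feature is
#' flagged non-normal when any cell rejects at `alpha` or is degenerate
#' (constant, or fewer than 3 values). The study routed two features
#' (effective time, peak delay) to nonparametric tests on this basis.
#'
#' @param table long feature table.
#' @param feature_name feature to check.
#' @param alpha per-cell significance level.
#' @return list: `normal` (logical), `cells` (per-cell p-values).
#' @export
check_normality <- function(table, feature_name, alpha = 0.05) {
  tbl <- as.data.table(table)[feature == feature_name & !is.na(value)]
  cells <- tbl[, .(p = {
    v <- value
    if (length(v) < 3L || sd(v) == 0) 0 else shapiro.test(v)$p.value
  }), by = .(message_type, day_type)]
  list(normal = all(cells$p > alpha), cells = cells[])
}

# orthonormal polynomial-free contrast basis for k levels (k x (k-1))
orth_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  sweep(cm, 2L, sqrt(colSums(cm^2)), "/")
}

# Mauchly sphericity test + Greenhouse-Geisser epsilon for transformed
# scores Z (n x p, p = effect df): Z = Y %*% C with orthonormal C
sphericity_stats <- function(Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  S <- stats::cov(Z)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (p * sum(lam^2))
  if (p < 2L || any(lam <= 0)) {
    return(list(W = NA_real_, chi2 = NA_real_, df = NA_real_,
                p = NA_real_, eps = if (p < 2L) 1 else eps))
  }
  W <- prod(lam) / (sum(lam) / p)^p
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * d * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       eps = eps)
}

#' Two-way repeated-measures ANOVA (message x day, fully within subjects)
#'
#' Decomposes within-subject variability into message (2 df), day (1 df) and
#' interaction (2 df) effects, each tested against its own
#' subject-by-effect error stratum. When Mauchly's test rejects sphericity
#' at `mauchly_alpha` for the message or interaction effect (the day effect
#' has 1 df and needs no correction), Greenhouse-Geisser-corrected degrees
#' of freedom and p-value are reported — the source of fractional degrees
#' of freedom in such tables. Effect size is generalized eta squared
#' (effect SS over effect SS plus all subject-level error SS).
#'
#' @param table long feature table.
#' @param feature_name outcome feature; participants with incomplete
#'   3 x 2 grids are dropped listwise.
#' @param gg one of `"mauchly"` (correct only when Mauchly rejects),
#'   `"always"`, `"never"`.
#' @param mauchly_alpha gate level for the Mauchly test.
#' @return object of class `anova_result`: `data.table` `effects` with
#'   columns effect, F, df1, df2, p, ges, corrected, plus `n` and the
#'   sphericity details.
#' @export
rm_anova_2way <- function(table, feature_name, gg = c("mauchly", "always",
                                                      "never"),
                          mauchly_alpha = 0.05) {
  gg <- match.arg(gg)
  Y <- feature_array(table, feature_name)
  n <- dim(Y)[1L]
  if (n < 2L) stop("need at least 2 complete participants")
  M <- 3L; D <- 2L
  gm <- mean(Y)
  m_s <- apply(Y, 1L, mean)
  m_m <- apply(Y, 2L, mean)
  m_d <- apply(Y, 3L, mean)
  m_sm <- apply(Y, c(1L, 2L), mean)
  m_sd <- apply(Y, c(1L, 3L), mean)
  m_md <- apply(Y, c(2L, 3L), mean)
  ss_s <- M * D * sum((m_s - gm)^2)
  ss_m <- n * D * sum((m_m - gm)^2)
  ss_d <- n * M * sum((m_d - gm)^2)
  ss_md <- n * sum((m_md - outer(m_m, rep(1, D)) -
                      outer(rep(1, M), m_d) + gm)^2)
  ss_sm <- D * sum((m_sm - outer(m_s, rep(1, M)) -
                      outer(rep(1, n), m_m) + gm)^2)
  ss_sd <- M * sum((m_sd - outer(m_s, rep(1, D)) -
                      outer(rep(1, n), m_d) + gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_smd <- ss_tot - ss_s - ss_m - ss_d - ss_md - ss_sm - ss_sd
  err_all <- ss_s + ss_sm + ss_sd + ss_smd
  # sphericity diagnostics on orthonormal contrast scores
  Cm <- orth_contrasts(M)
  Zm <- m_sm %*% Cm
  sph_m <- sphericity_stats(Zm)
  cd <- matrix(c(1, -1) / sqrt(2), 2L, 1L)
  Ymd <- matrix(aperm(Y, c(1L, 2L, 3L)), n, M * D)  # cols vary message fastest
  Cmd <- kronecker(cd, Cm)               # (M*D) x 2 with message fastest
  Zmd <- Ymd %*% Cmd
  sph_i <- sphericity_stats(Zmd)
  mk_effect <- function(name, ss_eff, df1, ss_err, df2, sph) {
    ms_eff <- ss_eff / df1
    ms_err <- ss_err / df2
    if (ms_err <= 0) stop("zero error variance for effect '", name,
                          "': F undefined")
    Fv <- ms_eff / ms_err
    correct <- !is.null(sph) && df1 > 1 &&
      ((gg == "always") ||
         (gg == "mauchly" && is.finite(sph$p) && sph$p < mauchly_alpha))
    eps <- if (correct) sph$eps else 1
    data.table(effect = name, F = Fv, df1 = df1 * eps, df2 = df2 * eps,
               p = pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               ges = ss_eff / (ss_eff + err_all),
               corrected = correct)
  }
  effects <- rbindlist(list(
    mk_effect("message", ss_m, M - 1, ss_sm, (n - 1) * (M - 1), sph_m),
    mk_effect("day", ss_d, D - 1, ss_sd, (n - 1) * (D - 1), NULL),
    mk_effect("interaction", ss_md, (M - 1) * (D - 1), ss_smd,
              (n - 1) * (M - 1) * (D - 1), sph_i)))
  structure(list(feature = feature_name, n = n, effects = effects,
                 ss = list(subject = ss_s, message = ss_m, day = ss_d,
                           interaction = ss_md, err_message = ss_sm,
                           err_day = ss_sd, err_interaction = ss_smd,
                           total = ss_tot),
                 sphericity = list(message = sph_m, interaction = sph_i)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("repeated-measures ANOVA for", x$feature, "(n =", x$n, ")\n")
  print(x$effects[, .(effect, F = round(F, 3), df1 = round(df1, 1),
                      df2 = round(df2, 1), p = signif(p, 3),
                      ges = signif(ges, 3), corrected)])
  invisible(x)
}

#' Friedman test of message type within one day type
#'
#' Ranks the three message-type values within each participant and tests
#' for a message effect, with the usual midrank tie correction. The effect
#' size is Kendall's coefficient of concordance
#' `W = chi2 / (n (k - 1))`.
#'
#' @param table long feature table.
#' @param feature_name outcome feature.
#' @param day_type `"weekday"` or `"weekend"`.
#' @return object of class `friedman_result`: `chi2`, `df` (= 2), `p`,
#'   `kendall_w`, `n`.
#' @export
friedman_by_daytype <- function(table, feature_name,
                                day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  dtp <- day_type
  tbl <- as.data.table(table)[feature == feature_name &
                                day_type == dtp & !is.na(value)]
  wide <- data.table::dcast(tbl, participant ~ message_type,
                            value.var = "value")
  have <- intersect(MESSAGE_TYPES, names(wide))
  if (length(have) < 3L) stop("need all 3 message types")
  wide <- wide[complete.cases(wide[, ..have])]
  n <- nrow(wide)
  if (n < 2L) stop("need at least 2 participants")
  k <- 3L
  R <- t(apply(as.matrix(wide[, ..have]), 1L, rank))
  colsum <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  chi2 <- if (denom <= 0) 0 else
    (k - 1) * sum((colsum - n * (k + 1) / 2)^2) / denom
  w <- chi2 / (n * (k - 1))
  structure(list(feature = feature_name, day_type = day_type, chi2 = chi2,
                 df = k - 1L,
                 p = pchisq(chi2, k - 1L, lower.tail = FALSE),
                 kendall_w = w, n = n),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test for %s (%s): chi2(%d) = %.3f, p = %.4g, W = %.3f, n = %d\n",
              x$feature, x$day_type, x$df, x$chi2, x$p, x$kendall_w, x$n))
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Paired t tests (or Wilcoxon signed-rank tests for features that failed
#' the normality gate) between the levels of a significant main effect,
#' with p-values multiplied by the number of comparisons and capped at 1.
#'
#' @param table long feature table.
#' @param feature_name outcome feature.
#' @param effect `"message"` (3 comparisons, values averaged over day
#'   types) or `"day"` (1 comparison, values averaged over message types);
#'   for `"message"` a `day_type` restriction may be supplied instead of
#'   averaging.
#' @param parametric paired t when `TRUE`, Wilcoxon signed-rank otherwise.
#' @param day_type optional restriction to one day type.
#' @return `data.table`: level_a, level_b, statistic, p_raw, p_adj, n.
#' @export
pairwise_posthoc <- function(table, feature_name,
                             effect = c("message", "day"),
                             parametric = TRUE, day_type = NULL) {
  effect <- match.arg(effect)
  tbl <- as.data.table(table)[feature == feature_name & !is.na(value)]
  if (!is.null(day_type)) {
    dtp <- day_type
    tbl <- tbl[day_type == dtp]
  }
  fac <- if (effect == "message") "message_type" else "day_type"
  other <- if (effect == "message") "day_type" else "message_type"
  avg <- tbl[, .(value = mean(value)), by = c("participant", fac)]
  wide <- data.table::dcast(avg,
                            stats::as.formula(paste("participant ~", fac)),
                            value.var = "value")
  levels_ <- setdiff(names(wide), "participant")
  pairs <- utils::combn(levels_, 2L, simplify = FALSE)
  out <- rbindlist(lapply(pairs, function(pr) {
    cc <- complete.cases(wide[, pr, with = FALSE])
    x <- wide[[pr[1L]]][cc]; y <- wide[[pr[2L]]][cc]
    d <- x - y
    if (length(d) < 2L || sd(d) == 0) {
      if (length(d) >= 2L && all(d == 0))
        return(data.table(level_a = pr[1L], level_b = pr[2L], statistic = 0,
                          p_raw = 1, n = length(d)))
      return(data.table(level_a = pr[1L], level_b = pr[2L],
                        statistic = NA_real_, p_raw = NA_real_,
                        n = length(d)))
    }
    tst <- if (parametric) t.test(x, y, paired = TRUE)
           else suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE))
    data.table(level_a = pr[1L], level_b = pr[2L],
               statistic = unname(tst$statistic), p_raw = tst$p.value,
               n = length(d))
  }))
  out[, p_adj := pmin(1, p_raw * length(pairs))]
  out[]
}

utils::globalVariables(c("p_adj", "p_raw", "n_min", "any_excl"))

#' Per-participant best message type (heterogeneity summary)
#'
#' Tabulates, per day type, which message library produced each
#' participant's largest mean steady-state response — the partition behind
#' the observation that no single message type is best for everyone.
#'
#' @param table long feature table containing `steady_state` rows.
#' @return `data.table`: day_type, message_type, n_best, fraction; every
#'   participant is assigned to exactly one type per day type (ties to the
#'   first library in affective/social-cognitive/quote order).
#' @export
best_message_summary <- function(table) {
  tbl <- as.data.table(table)[feature == "steady_state" & !is.na(value)]
  per <- tbl[, .(value = mean(value)), by = .(participant, day_type,
                                              message_type)]
  best <- per[, .SD[which.max(value)], by = .(participant, day_type)]
  out <- best[, .(n_best = .N), by = .(day_type, message_type)]
  totals <- best[, .(total = .N), by = day_type]
  out <- merge(out, totals, by = "day_type")
  out[, fraction := n_best / total]
  setorder(out, day_type, -n_best)
  out[]
}

utils::globalVariables(c("fraction", "n_best", "total"))
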