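# shared fixtures built in code

# first-order dynamics embedded in the order-5 parameterisation:
# a1 = pole, b_channel(lag0) = gain, everything else zero
first_order_coeffs <- function(pole = 0.5, gain = 10,
                               channel = "affective", a0 = 0) {
  b <- matrix(0, 3, 6)
  b[match(channel, c("affective", "social_cognitive", "quote")), 1] <- gain
  arx_coefficients(a0 = a0, a = c(pole, 0, 0, 0, 0), b = b)
}

toy_spec <- function(id = "P1", noise_sd = 10, pole_wd = 0.4, pole_we = 0.6,
                     hr_dropout = 0, nonwear = 0,
                     window_start = 480L, window_end = 1200L) {
  mk <- function(pole) {
    b <- rbind(c(10, 0, 0, -2, -2, -2),
               c(20, 0, 0, 0, 0, 0),
               c(-5, 0, 0, 3, 0, 0))
    arx_coefficients(a0 = 150 * (1 - pole), a = c(pole, 0, 0, 0, 0), b = b)
  }
  participant_spec(id, mk(pole_wd), mk(pole_we),
                   window_start = window_start, window_end = window_end,
                   baseline_rate = 10, noise_sd = noise_sd,
                   hr_dropout_prob = hr_dropout,
                   nonwear_blocks_per_week = nonwear)
}

# one day's minute table on a gap-free grid, all worn, constant steps
flat_day_minutes <- function(lo = 360L, hi = 1320L, steps = 5L) {
  data.table::data.table(minute = lo:(hi - 1L),
                         steps = as.numeric(steps), hr_present = 1L)
}

# mark [from, to] (minute values) as missing: zero steps, no heart rate
punch_gap <- function(dt, from, to) {
  dt <- data.table::copy(dt)
  dt[minute >= from & minute <= to,
     `:=`(steps = 0, hr_present = 0L)]
  dt
}

# balanced long feature table for the statistics module
make_feature_table <- function(n = 10, feature_name = "rise_time",
                               day_shift = 0, message_shift = c(0, 0, 0),
                               sd = 10, mean = 60) {
  pts <- sprintf("S%02d", seq_len(n))
  ft <- data.table::CJ(participant = pts,
                       message_type = c("affective", "social_cognitive",
                                        "quote"),
                       day_type = c("weekday", "weekend"))
  ft[, feature := feature_name]
  shift <- message_shift[match(ft$message_type,
                               c("affective", "social_cognitive", "quote"))]
  ft[, value := stats::rnorm(.N, mean, sd) + shift +
        ifelse(day_type == "weekend", day_shift, 0)]
  ft
}

# deterministic dataset with a sphericity violation in the message factor;
# expected values frozen from an independent oracle run
gg_fixture <- function() {
  set.seed(42)
  n <- 12
  pts <- sprintf("S%02d", seq_len(n))
  base <- rnorm(n, 0, 5)
  m1 <- base + rnorm(n, 0, 1)
  m2 <- base + rnorm(n, 5, 8)
  m3 <- base + rnorm(n, 2, 15)
  data.table::rbindlist(lapply(1:2, function(d) data.table::data.table(
    participant = rep(pts, 3),
    message_type = rep(c("affective", "social_cognitive", "quote"),
                       each = n),
    day_type = c("weekday", "weekend")[d],
    feature = "x",
    value = c(m1, m2, m3) + rnorm(3 * n, ifelse(d == 2, 3, 0), 2))))
}
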