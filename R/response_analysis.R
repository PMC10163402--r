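#' Simulate the impulse and cumulative step response to one message
#'
#' Feeds a single unit input on one message channel at epoch 0 through the
#' fitted ARX dynamics and iterates for 40 epochs (600 minutes). The
#' response is the deviation from the no-message trajectory, so the
#' intercept and baseline cancel and are ignored. The cumulative curve is
#' the running sum of the impulse curve; its value at the horizon is the
#' total expected step effect of one message (the steady state).
#'
#' @param model an `arx_model`, or [arx_coefficients] directly.
#' @param channel one of `"affective"`, `"social_cognitive"`, `"quote"`.
#' @param horizon number of epochs simulated (default 40 = 600 min).
#' @return object of class `response_curve`: `channel`, `horizon`, `time`
#'   (minutes after receipt, starting at 0), `impulse`, `cumulative`,
#'   `unstable` flag; error-bound slots `impulse_lo/hi`,
#'   `cumulative_lo/hi` are `NULL` until [estimate_error_bounds] fills
#'   them.
#' @export
simulate_impulse <- function(model, channel = MESSAGE_TYPES[1],
                             horizon = 40L) {
  coeffs <- if (inherits(model, "arx_model")) model$coeffs else model
  stopifnot(inherits(coeffs, "arx_coefficients"))
  channel <- match.arg(channel, MESSAGE_TYPES)
  imp <- impulse_recursion(coeffs$a, coeffs$b[channel, ], horizon)
  structure(list(channel = channel, horizon = as.integer(horizon),
                 time = EPOCH_MIN * (seq_len(horizon) - 1L),
                 impulse = imp, cumulative = cumsum(imp),
                 impulse_lo = NULL, impulse_hi = NULL,
                 cumulative_lo = NULL, cumulative_hi = NULL,
                 unstable = arx_spectral_radius(coeffs) >= 1),
            class = "response_curve")
}

# ARX recursion for a unit impulse on one channel, intercept suppressed
impulse_recursion <- function(a, brow, horizon) {
  p <- length(a)
  y <- numeric(horizon)
  for (k in seq_len(horizon)) {
    acc <- if (k <= length(brow)) brow[k] else 0   # u(0)=1 hits lag k-1
    for (i in seq_len(min(p, k - 1L)))
      acc <- acc + a[i] * y[k - i]
    y[k] <- acc
  }
  unname(y)
}

#' @export
print.response_curve <- function(x, ...) {
  cat("response curve (", x$channel, "), horizon ", x$horizon,
      " epochs\n  steady state: ", format(x$cumulative[x$horizon],
                                          digits = 4), sep = "")
  if (x$unstable) cat("  [unstable]")
  cat("\n")
  invisible(x)
}

#' Attach parametric-bootstrap error bounds to a response curve
#'
#' Draws `B` coefficient vectors from the fitted model's approximate
#' sampling distribution `N(beta_hat, cov)`, simulates each impulse and
#' cumulative curve, and takes pointwise percentile bounds. A
#' non-positive-semidefinite covariance (numerically possible after column
#' dropping) is repaired by clipping negative eigenvalues at zero, with a
#' warning.
#'
#' @param model an `arx_model` with covariance available.
#' @param channel message channel.
#' @param B number of bootstrap draws.
#' @param level coverage of the pointwise band (default 0.95).
#' @param horizon epochs simulated.
#' @return a `response_curve` with `impulse_lo/hi` and `cumulative_lo/hi`
#'   filled; bounds always bracket the point estimate.
#' @export
estimate_error_bounds <- function(model, channel = MESSAGE_TYPES[1],
                                  B = 500L, level = 0.95, horizon = 40L) {
  stopifnot(inherits(model, "arx_model"), B >= 2L)
  channel <- match.arg(channel, MESSAGE_TYPES)
  curve <- simulate_impulse(model, channel, horizon)
  covb <- (model$cov + t(model$cov)) / 2
  ev <- eigen(covb, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    warning("coefficient covariance not PSD; clipping negative eigenvalues")
  lam <- pmax(ev$values, 0)
  hl <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  # only the output lags and this channel's input lags shape the response
  a_idx <- 2:(ARX_ORDER + 1L)
  ch <- match(channel, MESSAGE_TYPES)
  b_idx <- (ARX_ORDER + 1L) + (ch - 1L) * (ARX_ORDER + 1L) + 1:(ARX_ORDER + 1L)
  beta0 <- unname(model$beta)
  imp <- matrix(0, B, horizon)
  for (bb in seq_len(B)) {
    beta <- beta0 + drop(hl %*% rnorm(N_COEF))
    imp[bb, ] <- impulse_recursion(beta[a_idx], beta[b_idx], horizon)
  }
  cum <- t(apply(imp, 1L, cumsum))
  alpha <- (1 - level) / 2
  qs <- function(m, pr) apply(m, 2L, quantile, probs = pr, names = FALSE)
  curve$impulse_lo <- pmin(qs(imp, alpha), curve$impulse)
  curve$impulse_hi <- pmax(qs(imp, 1 - alpha), curve$impulse)
  curve$cumulative_lo <- pmin(qs(cum, alpha), curve$cumulative)
  curve$cumulative_hi <- pmax(qs(cum, 1 - alpha), curve$cumulative)
  curve
}

#' Extract the seven response features from a curve
#'
#' From the impulse curve: initial delay (first epoch at which the impulse
#' error band excludes zero; 0 when no epoch does), peak magnitude
#' (largest absolute momentary effect) and peak delay (time of that peak,
#' earliest epoch on ties). From the cumulative curve: steady state (value
#' at the horizon), rise time (time to advance from 10% to 90% of steady
#' state), settling time (earliest time after which the curve stays within
#' 95%-105% of steady state) and effective time (total time the cumulative
#' error band excludes zero). Crossings are evaluated on the
#' cumulative-to-steady-state ratio so negative steady states are handled
#' symmetrically. All time features are multiples of 15 minutes within
#' [0, 600].
#'
#' @param curve a `response_curve`; band-based features (initial delay,
#'   effective time) require bounds from [estimate_error_bounds] and are
#'   `NA` otherwise.
#' @return object of class `feature_set`: named list of the 7 features plus
#'   `flags`.
#' @export
extract_features <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  H <- curve$horizon
  imp <- curve$impulse
  cum <- curve$cumulative
  flags <- character(0)
  if (curve$unstable) flags <- c(flags, "unstable")
  ss <- cum[H]
  peak_idx <- which.max(abs(imp))
  peak_magnitude <- abs(imp[peak_idx])
  peak_delay <- EPOCH_MIN * (peak_idx - 1L)
  has_bands <- !is.null(curve$impulse_lo)
  initial_delay <- if (has_bands) {
    outside <- curve$impulse_lo > 0 | curve$impulse_hi < 0
    if (any(outside)) EPOCH_MIN * (which(outside)[1L] - 1L) else 0
  } else NA_real_
  effective_time <- if (has_bands) {
    EPOCH_MIN * sum(curve$cumulative_lo > 0 | curve$cumulative_hi < 0)
  } else NA_real_
  if (ss == 0) {
    flags <- c(flags, "zero_steady_state")
    rise_time <- settling_time <- NA_real_
  } else {
    ratio <- cum / ss
    i10 <- which(ratio >= 0.1)[1L]
    i90 <- which(ratio >= 0.9)[1L]
    rise_time <- if (is.na(i10) || is.na(i90)) NA_real_
                 else EPOCH_MIN * (i90 - i10)
    inside <- ratio >= 0.95 & ratio <= 1.05
    # earliest index from which the ratio never leaves the band
    stay <- rev(cumprod(rev(inside))) > 0
    settling_time <- if (any(stay)) EPOCH_MIN * (which(stay)[1L] - 1L)
                     else NA_real_
    if (is.na(rise_time) || is.na(settling_time))
      flags <- c(flags, "nonconvergent")
  }
  structure(list(initial_delay = initial_delay,
                 peak_magnitude = peak_magnitude,
                 peak_delay = peak_delay,
                 steady_state = ss,
                 rise_time = rise_time,
                 settling_time = settling_time,
                 effective_time = effective_time,
                 flags = flags),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "flags")])
  print(round(vals, 3))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Features for every message channel of one fitted model
#'
#' @param model an `arx_model`.
#' @param B bootstrap draws for error bounds; `B = 0` skips bounds (the
#'   band-based features come back `NA`), which is much faster when only
#'   peak/steady-state/rise/settling features are needed.
#' @param horizon epochs simulated.
#' @return named list of `feature_set`, one per message type.
#' @export
model_features <- function(model, B = 500L, horizon = 40L) {
  out <- lapply(MESSAGE_TYPES, function(ch) {
    curve <- if (B > 0L) estimate_error_bounds(model, ch, B = B,
                                               horizon = horizon)
             else simulate_impulse(model, ch, horizon)
    extract_features(curve)
  })
  names(out) <- MESSAGE_TYPES
  out
}

#' Assemble a long-format feature table across participants
#'
#' @param models named list (participant id) of lists with `weekday` /
#'   `weekend` `arx_model`s (as from [fit_switched_models]).
#' @param B bootstrap draws per curve (0 to skip band features).
#' @param horizon epochs simulated.
#' @return `data.table` with columns `participant`, `message_type`,
#'   `day_type`, `feature`, `value` — the package's FeatureTable.
#' @export
feature_table <- function(models, B = 0L, horizon = 40L) {
  feat_names <- c("initial_delay", "peak_magnitude", "peak_delay",
                  "steady_state", "rise_time", "settling_time",
                  "effective_time")
  rows <- list()
  for (pid in names(models)) {
    for (dt in c("weekday", "weekend")) {
      m <- models[[pid]][[dt]]
      if (is.null(m)) next
      fs <- model_features(m, B = B, horizon = horizon)
      for (ch in MESSAGE_TYPES)
        rows[[length(rows) + 1L]] <- data.table(
          participant = pid, message_type = ch, day_type = dt,
          feature = feat_names,
          value = unlist(fs[[ch]][feat_names], use.names = FALSE))
    }
  }
  rbindlist(rows)
}
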