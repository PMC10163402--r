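#' Merge minute-level activity, message log and availability window
#'
#' Restricts each day's minute records to the availability window extended by
#' 2 hours on each side (clipped at midnight, because days are modeled
#' independently) and drops messages that were scheduled but never displayed
#' on the device (`delivered = FALSE`) as well as messages outside the
#' window.
#'
#' @param minutes `data.table` with columns `date` (Date), `minute`
#'   (0-1439), `steps`, `hr_present`.
#' @param messages `data.table` with columns `date`, `minute`, `library`,
#'   `delivered`; may be empty.
#' @param window list/row with `window_start`, `window_end` (minutes since
#'   midnight).
#' @return list with elements `minutes` (restricted, time-ordered) and
#'   `messages` (delivered, in-window). Days with no minute data inside the
#'   extended window are dropped with a message.
#' @export
merge_streams <- function(minutes, messages, window) {
  minutes <- as.data.table(minutes)
  messages <- as.data.table(messages)
  ext_start <- max(0L, window$window_start - 120L)
  ext_end <- min(1440L, window$window_end + 120L)
  if (anyDuplicated(minutes[, .(date, minute)]))
    stop("duplicate minute timestamps in input")
  kept <- minutes[minute >= ext_start & minute < ext_end]
  setorder(kept, date, minute)
  dropped_days <- setdiff(as.character(unique(minutes$date)),
                          as.character(unique(kept$date)))
  if (length(dropped_days))
    message("dropping day(s) with no in-window data: ",
            paste(dropped_days, collapse = ", "))
  msg <- if (nrow(messages)) {
    messages[delivered %in% c(TRUE, 1L) &
               minute >= window$window_start & minute < window$window_end]
  } else messages
  list(minutes = kept, messages = msg)
}

#' Classify missing minutes and interpolate short gaps
#'
#' A minute is missing iff it recorded zero steps while the heart-rate
#' stream was absent. Maximal missing runs of up to 3 minutes with observed
#' values on both flanks are filled by linear interpolation between those
#' flanking step counts; longer runs, and runs touching either end of the
#' day's record, are marked excluded and invalidate any epoch containing
#' them.
#'
#' @param day_minutes one day's `data.table` with columns `minute`, `steps`,
#'   `hr_present`, time-ordered and gap-free.
#' @param max_fill longest run length eligible for interpolation (minutes).
#' @return the table with `steps` filled where interpolated plus logical
#'   columns `missing_flag` (classified missing) and `excluded` (dropped from
#'   modeling).
#' @export
classify_and_interpolate <- function(day_minutes, max_fill = 3L) {
  dt <- copy(as.data.table(day_minutes))
  setorder(dt, minute)
  if (nrow(dt) > 1L && any(diff(dt$minute) != 1L))
    stop("minute index must be gap-free within a day")
  dt[, missing_flag := steps == 0 & !(hr_present %in% c(TRUE, 1L))]
  dt[, excluded := FALSE]
  dt[, steps := as.numeric(steps)]
  r <- rle(dt$missing_flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- nrow(dt)
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]; len <- e - s + 1L
    if (len <= max_fill && s > 1L && e < n) {
      left <- dt$steps[s - 1L]; right <- dt$steps[e + 1L]
      w <- seq_len(len) / (len + 1)
      dt[s:e, steps := left + w * (right - left)]
    } else {
      dt[s:e, excluded := TRUE]
    }
  }
  dt[]
}

#' Aggregate one day's minutes into a 15-minute epoch series
#'
#' Epochs are anchored at clock quarter hours. An epoch is valid iff all 15
#' of its minutes are present and none is excluded; `y` is the sum of
#' (possibly interpolated) steps and `u` flags delivery of at least one
#' message per library inside the epoch.
#'
#' @param day_minutes output of [classify_and_interpolate] for one day.
#' @param day_messages delivered messages for the same day (`minute`,
#'   `library`).
#' @param participant_id,date metadata carried on the result.
#' @return object of class `epoch_series`: list with `participant_id`,
#'   `date`, `day_type` ("weekday"/"weekend"), `epoch_start`, `y`, `u`
#'   (n x 3 binary matrix), `valid`, `d` (= 15).
#' @export
aggregate_epochs <- function(day_minutes, day_messages = NULL,
                             participant_id = NA_character_, date = NA) {
  dt <- as.data.table(day_minutes)
  lo <- min(dt$minute); hi <- max(dt$minute) + 1L
  first <- as.integer(ceiling(lo / EPOCH_MIN) * EPOCH_MIN)
  starts <- seq.int(first, hi - EPOCH_MIN, by = EPOCH_MIN)
  starts <- starts[starts + EPOCH_MIN <= hi]
  if (!length(starts)) stop("day too short for a single epoch")
  dt[, epoch := (minute %/% EPOCH_MIN) * EPOCH_MIN]
  agg <- dt[epoch %in% starts,
            .(y = sum(steps), n_min = .N, any_excl = any(excluded)),
            by = epoch][order(epoch)]
  agg <- agg[data.table(epoch = starts), on = "epoch"]
  valid <- !is.na(agg$n_min) & agg$n_min == EPOCH_MIN & !agg$any_excl
  u <- matrix(0L, length(starts), 3L, dimnames = list(NULL, MESSAGE_TYPES))
  if (!is.null(day_messages) && nrow(as.data.table(day_messages))) {
    msg <- as.data.table(day_messages)
    ep <- findInterval(msg$minute, starts)
    ok <- ep >= 1L & msg$minute < starts[pmax(ep, 1L)] + EPOCH_MIN
    for (r in which(ok)) u[ep[r], as.character(msg$library[r])] <- 1L
  }
  structure(list(participant_id = participant_id, date = as.Date(date),
                 day_type = if (is_weekend(date)) "weekend" else "weekday",
                 epoch_start = starts,
                 y = ifelse(valid, agg$y, NA_real_),
                 u = u, valid = valid, d = EPOCH_MIN),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat("epoch series: ", x$participant_id, " ", format(x$date), " (",
      x$day_type, "), ", length(x$y), " epochs, ", sum(x$valid),
      " valid, ", sum(x$u), " message epochs\n", sep = "")
  invisible(x)
}

#' Partition epoch series by day type
#'
#' @param series list of `epoch_series`.
#' @return list with components `weekday` and `weekend` (Saturday/Sunday).
#' @export
split_day_type <- function(series) {
  types <- vapply(series, `[[`, "", "day_type")
  list(weekday = series[types == "weekday"],
       weekend = series[types == "weekend"])
}

#' Preprocess one participant from raw tables to epoch series
#'
#' Convenience composition of [merge_streams], [classify_and_interpolate]
#' and [aggregate_epochs] over all days.
#'
#' @inheritParams merge_streams
#' @param participant_id carried onto each series.
#' @return list of `epoch_series`, one per day with in-window data.
#' @export
preprocess_participant <- function(minutes, messages, window,
                                   participant_id = NA_character_) {
  merged <- merge_streams(minutes, messages, window)
  dates <- unique(merged$minutes$date)
  lapply(dates, function(dd) {
    dm <- classify_and_interpolate(merged$minutes[date == dd])
    msg <- if (nrow(merged$messages)) merged$messages[date == dd] else NULL
    aggregate_epochs(dm, msg, participant_id = participant_id, date = dd)
  })
}

# parse "YYYY-MM-DD HH:MM:SS" stamps into date + minute-of-day
parse_stamp <- function(ts) {
  list(date = as.Date(substr(ts, 1L, 10L)),
       minute = as.integer(substr(ts, 12L, 13L)) * 60L +
         as.integer(substr(ts, 15L, 16L)))
}

#' Read one participant's cohort bundle from disk
#'
#' Reads the CSV/JSON files written by [generate_cohort] (or real exports in
#' the same layout) into the in-memory tables used by the preprocessing
#' functions.
#'
#' @param dir directory holding the bundle.
#' @param participant_id participant file prefix.
#' @return list with `minutes`, `messages`, `window`, `participant_id`.
#' @export
read_participant_bundle <- function(dir, participant_id) {
  pfile <- function(suffix) file.path(dir, paste0(participant_id, suffix))
  mins <- fread(pfile("_minutes.csv"))
  st <- parse_stamp(mins$timestamp)
  minutes <- data.table(date = st$date, minute = st$minute,
                        steps = mins$steps, hr_present = mins$hr_present)
  msg_raw <- fread(pfile("_messages.csv"))
  messages <- if (nrow(msg_raw)) {
    stm <- parse_stamp(msg_raw$timestamp)
    data.table(date = stm$date, minute = stm$minute,
               library = msg_raw$library,
               delivered = as.logical(msg_raw$delivered))
  } else data.table(date = as.Date(character()), minute = integer(),
                    library = character(), delivered = logical())
  window <- jsonlite::read_json(pfile("_window.json"), simplifyVector = TRUE)
  list(minutes = minutes, messages = messages, window = window,
       participant_id = participant_id)
}
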