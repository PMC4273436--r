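#' Activity record for one monitor channel
#'
#' Wraps a vector of per-minute beam-crossing counts spanning whole days,
#' with the experimental phase of each day (baseline, activation, recovery)
#' and a 12:12 light-dark cycle starting at lights-on.
#'
#' @param channel Channel/fly identifier.
#' @param counts Integer vector of 1-min activity counts; length must be a
#'   multiple of 1440 (complete days only; missing bins are an error, no
#'   imputation is done).
#' @param phases Named list mapping phase names to day numbers, e.g.
#'   `list(baseline = 1:3, activation = 4:5, recovery = 6:7)`.
#' @param lights_on_minute Minute of day (0-1439) at which lights turn on;
#'   the light phase lasts 720 min. Day 1 starts at minute 0 of the record.
#' @return An object of class `activity_record`.
#' @export
activity_record <- function(channel, counts,
                            phases = list(baseline = 1:3, activation = 4:5,
                                          recovery = 6:7),
                            lights_on_minute = 0) {
  counts <- as.integer(counts)
  if (anyNA(counts)) {
    bad <- which(is.na(counts))
    stop(sprintf("missing activity bins at minutes %d-%d (no imputation)",
                 min(bad), max(bad)))
  }
  if (any(counts < 0)) stop("activity counts must be non-negative")
  if (length(counts) %% 1440 != 0)
    stop(sprintf("counts span %d minutes, not a whole number of 1440-min days",
                 length(counts)))
  n_days <- length(counts) %/% 1440
  phase_days <- sort(as.integer(unlist(phases, use.names = FALSE)))
  if (!identical(phase_days, seq_len(n_days)))
    stop("phases must label each of the record's days exactly once, contiguously")
  stopifnot(lights_on_minute >= 0, lights_on_minute < 1440)
  structure(list(channel = channel, counts = counts, n_days = n_days,
                 phases = phases, lights_on_minute = lights_on_minute),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> channel %s: %d days, %d total counts\n",
              as.character(x$channel), x$n_days, sum(x$counts)))
  invisible(x)
}

phase_of_day <- function(record) {
  out <- rep(NA_character_, record$n_days)
  for (ph in names(record$phases)) out[record$phases[[ph]]] <- ph
  out
}

# TRUE for minutes (1-based) falling in the light phase of the 12:12 cycle
light_mask <- function(record) {
  minute_of_day <- (seq_along(record$counts) - 1L) %% 1440L
  rel <- (minute_of_day - record$lights_on_minute) %% 1440L
  rel < 720L
}

# logical vector: minute is inside a sleep bout
sleep_mask <- function(record, min_bout = 5) {
  asleep <- rep(FALSE, length(record$counts))
  bouts <- detect_sleep_bouts(record, min_bout)
  for (i in seq_len(nrow(bouts)))
    asleep[bouts$start[i] + seq_len(bouts$duration[i]) - 1L] <- TRUE
  asleep
}

#' Detect sleep bouts
#'
#' Sleep is scored as any maximal run of consecutive minutes with zero
#' activity counts lasting at least `min_bout` minutes (default 5). Shorter
#' inactive runs contribute no sleep.
#'
#' @param record An [activity_record()].
#' @param min_bout Minimum bout duration in minutes.
#' @return A data frame with one row per bout: `start` (1-based minute
#'   index), `duration` (min), `day`, and `light_phase` (`"light"`/`"dark"`)
#'   at bout start.
#' @export
detect_sleep_bouts <- function(record, min_bout = 5) {
  r <- rle(record$counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  light <- light_mask(record)
  data.frame(
    start = starts[keep],
    duration = r$lengths[keep],
    day = (starts[keep] - 1L) %/% 1440L + 1L,
    light_phase = ifelse(light[starts[keep]], "light", "dark")
  )[order(starts[keep]), , drop = FALSE]
}

#' Daily sleep amounts
#'
#' Sums sleep-bout minutes within each day, split into the light and dark
#' halves of the 12:12 cycle; bouts spanning a day or light boundary are
#' apportioned by the minutes falling on each side.
#'
#' @inheritParams detect_sleep_bouts
#' @return A data frame with one row per day: `day`, `phase`, `sleep_min`,
#'   `light_sleep_min`, `dark_sleep_min`.
#' @export
daily_sleep <- function(record, min_bout = 5) {
  asleep <- sleep_mask(record, min_bout)
  light <- light_mask(record)
  day <- factor((seq_along(asleep) - 1L) %/% 1440L + 1L,
                levels = seq_len(record$n_days))
  data.frame(
    day = seq_len(record$n_days),
    phase = phase_of_day(record),
    sleep_min = as.integer(tapply(asleep, day, sum)),
    light_sleep_min = as.integer(tapply(asleep & light, day, sum)),
    dark_sleep_min = as.integer(tapply(asleep & !light, day, sum))
  )
}

#' Cohort sleep profile
#'
#' Mean sleep minutes per 30-min bin (48 bins/day) across flies, per day.
#'
#' @param records A list of [activity_record()] objects with equal day
#'   counts.
#' @param bin Bin width in minutes (must divide 1440).
#' @param min_bout Minimum sleep-bout duration in minutes.
#' @return A data frame `day`, `bin` (1-based within day), `t_min` (bin
#'   start minute within day), `mean_sleep_min`.
#' @export
sleep_profile <- function(records, bin = 30, min_bout = 5) {
  stopifnot(length(records) >= 1, 1440 %% bin == 0)
  n_days <- records[[1]]$n_days
  per_fly <- vapply(records, function(rec) {
    stopifnot(rec$n_days == n_days)
    asleep <- sleep_mask(rec, min_bout)
    bin_id <- (seq_along(asleep) - 1L) %/% bin
    bin_id <- factor(bin_id, levels = seq_len(n_days * 1440 / bin) - 1L)
    as.numeric(tapply(asleep, bin_id, sum))
  }, numeric(n_days * 1440 / bin))
  mean_sleep <- rowMeans(per_fly)
  bins_per_day <- 1440 / bin
  data.frame(
    day = rep(seq_len(n_days), each = bins_per_day),
    bin = rep(seq_len(bins_per_day), times = n_days),
    t_min = rep((seq_len(bins_per_day) - 1) * bin, times = n_days),
    mean_sleep_min = mean_sleep
  )
}

#' Percent change in sleep under activation
#'
#' `100 * (mean daily sleep over the activation days - baseline-day sleep) /
#' baseline-day sleep`. Negative values indicate decreased sleep during
#' activation. Flies with zero baseline sleep have an undefined change and
#' return `NA` with a warning.
#'
#' @param record An [activity_record()].
#' @param baseline_day Day used as baseline (default 3, the last baseline
#'   day).
#' @param activation_days Days averaged as the activation measurement.
#' @param min_bout Minimum sleep-bout duration in minutes.
#' @return Percent change (a single number), or `NA` if undefined.
#' @export
percent_sleep_change <- function(record, baseline_day = 3,
                                 activation_days = c(4, 5), min_bout = 5) {
  ds <- daily_sleep(record, min_bout)
  stopifnot(baseline_day %in% ds$day, all(activation_days %in% ds$day))
  base <- ds$sleep_min[ds$day == baseline_day]
  act <- mean(ds$sleep_min[ds$day %in% activation_days])
  if (base == 0) {
    warning(sprintf("channel %s: zero baseline sleep; percent change undefined",
                    as.character(record$channel)))
    return(NA_real_)
  }
  100 * (act - base) / base
}

#' Waking activity
#'
#' Beam crossings per minute awake: total counts divided by the number of
#' minutes not inside any sleep bout.
#'
#' @inheritParams detect_sleep_bouts
#' @return Crossings per awake minute, or `NA` (with a warning) if the fly
#'   was never awake.
#' @export
waking_activity <- function(record, min_bout = 5) {
  awake <- !sleep_mask(record, min_bout)
  if (!any(awake)) {
    warning(sprintf("channel %s: no awake minutes; waking activity undefined",
                    as.character(record$channel)))
    return(NA_real_)
  }
  sum(record$counts) / sum(awake)
}

#' Flag channels that look dead
#'
#' A trailing run of zero counts lasting at least `min_trailing_hours` up to
#' the end of the record is the standard signature of a fly that died in the
#' tube; such channels should be excluded rather than scored as sleeping.
#'
#' @param record An [activity_record()].
#' @param min_trailing_hours Length of terminal inactivity that triggers the
#'   flag.
#' @return `TRUE` if the channel is flagged.
#' @export
is_dead_channel <- function(record, min_trailing_hours = 12) {
  r <- rle(record$counts == 0L)
  n <- length(r$values)
  r$values[n] && r$lengths[n] >= min_trailing_hours * 60
}
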