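# Independent oracles and small builders used across the test files.

# build a single-fly trajectory table from coordinate vectors
make_traj <- function(x, y, fps = 30, fly = "f1", frame0 = 0L,
                      frames = NULL) {
  if (is.null(frames)) frames <- frame0 + seq_along(x) - 1L
  data.frame(frame = as.integer(frames), fly_id = fly,
             t_s = frames / fps, x_mm = x, y_mm = y,
             stringsAsFactors = FALSE)
}

# brute-force per-frame state-machine scan for choice-zone events: a direct
# transcription of the event definition, independent of the rle-based
# segmentation in the package
oracle_choice_events <- function(traj, config = arena_config(),
                                 schedule = default_schedule(), early = 1) {
  span <- schedule_span(schedule)
  traj <- traj[traj$t_s >= span[1] - 1e-9 & traj$t_s <= span[2] + 1e-9, ,
               drop = FALSE]
  rows <- list()
  for (fly in unique(traj$fly_id)) {
    d <- traj[traj$fly_id == fly, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    n <- nrow(d)
    inz <- in_choice_zone(d$x_mm, d$y_mm, config)
    if (all(inz)) next
    i <- 1L
    while (i <= n) {
      contig_prev <- i > 1L && d$frame[i] == d$frame[i - 1L] + 1L
      is_start <- inz[i] && (i == 1L || !contig_prev || !inz[i - 1L])
      if (!is_start) { i <- i + 1L; next }
      j <- i
      while (j < n && d$frame[j + 1L] == d$frame[j] + 1L && inz[j + 1L])
        j <- j + 1L
      has_entry <- i > 1L && d$frame[i] == d$frame[i - 1L] + 1L
      has_exit <- j < n && d$frame[j + 1L] == d$frame[j] + 1L
      entry_side <- exit_side <- NA_character_
      censor <- NA_character_
      if (!has_entry) {
        censor <- "entry_gap"
      } else {
        ip <- i - 1L
        ep <- epoch_at(d$t_s[ip], schedule)
        lit_set <- schedule$lit[[ep]]
        entry_side <- illumination_state(d$x_mm[ip], d$y_mm[ip], d$t_s[ip],
                                         schedule, config)
        if (!has_exit) {
          censor <- "track_loss"
        } else {
          ix <- j + 1L
          exit_side <- illumination_state(d$x_mm[ix], d$y_mm[ix], d$t_s[ix],
                                          schedule, config)
          if (epoch_at(d$t_s[ix], schedule) != ep) censor <- "epoch_boundary"
          else if (length(lit_set) == 0) censor <- "dark_epoch"
          else if (length(lit_set) == 4) censor <- "uniform_light"
          else if (d$t_s[ip] - schedule$t_start[ep] < early)
            censor <- "early_epoch"
        }
      }
      outcome <- if (!is.na(censor)) "censored"
                 else if (exit_side != entry_side) "crossing"
                 else "turnaround"
      rows[[length(rows) + 1L]] <- data.frame(
        fly_id = fly, t_entry = d$t_s[i],
        t_exit = if (has_exit) d$t_s[j + 1L] else NA_real_,
        entry_side = entry_side, exit_side = exit_side,
        outcome = outcome, censor_reason = censor,
        stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$fly_id, out$t_entry), , drop = FALSE]
}

# compare implementation events with the oracle on boundaries, sides and
# outcomes
expect_events_match_oracle <- function(traj, config = arena_config(),
                                       schedule = default_schedule()) {
  got <- suppressWarnings(segment_choice_events(traj, config, schedule))
  got <- got[order(got$fly_id, got$t_entry),
             c("fly_id", "t_entry", "t_exit", "entry_side", "exit_side",
               "outcome", "censor_reason")]
  rownames(got) <- NULL
  want <- oracle_choice_events(traj, config, schedule)
  if (is.null(want)) {
    expect_equal(nrow(got), 0L)
    return(invisible(TRUE))
  }
  rownames(want) <- NULL
  expect_equal(got, want)
}

# explicit scan for sleep bouts: runs of zero minutes of length >= min_bout
oracle_sleep_bouts <- function(counts, min_bout = 5) {
  starts <- integer(0)
  durations <- integer(0)
  run <- 0L
  for (m in seq_along(counts)) {
    if (counts[m] == 0L) {
      run <- run + 1L
    } else {
      if (run >= min_bout) {
        starts <- c(starts, m - run)
        durations <- c(durations, run)
      }
      run <- 0L
    }
  }
  if (run >= min_bout) {
    starts <- c(starts, length(counts) + 1L - run)
    durations <- c(durations, run)
  }
  data.frame(start = starts, duration = durations)
}

# single-day activity record with given count vector
day_record <- function(counts, n_days = 1,
                       phases = setNames(list(seq_len(n_days)), "baseline")) {
  activity_record("ch01", counts, phases = phases)
}

# minute-level sleep mask reconstructed from the detected bouts
sleep_mask_for_test <- function(rec) {
  b <- detect_sleep_bouts(rec)
  m <- rep(FALSE, length(rec$counts))
  for (i in seq_len(nrow(b)))
    m[b$start[i] + seq_len(b$duration[i]) - 1L] <- TRUE
  m
}
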