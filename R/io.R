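#' Read a trajectory CSV
#'
#' Reads tracker output in the package dialect: a CSV with header
#' `frame,fly_id,t_s,x_mm,y_mm`, one row per fly per frame. Parsing is
#' strict: malformed or duplicate rows are errors (with line numbers), and a
#' unit sanity check rejects files whose positions are implausibly small for
#' the configured arena (e.g. cm values in a mm column) rather than
#' rescaling silently.
#'
#' @param path Path to the CSV file.
#' @param config An [arena_config()] used for bounds and unit checks.
#' @param check_units If `TRUE`, error when all positions fall within 15% of
#'   the arena radius.
#' @return A validated trajectory table (see [validate_trajectories()]).
#' @export
read_trajectories <- function(path, config = arena_config(),
                              check_units = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  traj <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("frame", "fly_id", "t_s", "x_mm", "y_mm")
  if (!identical(names(traj), expected))
    stop("header must be exactly: ", paste(expected, collapse = ","))
  for (col in c("frame", "t_s", "x_mm", "y_mm")) {
    bad <- which(is.na(suppressWarnings(as.numeric(traj[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("malformed value in column '%s' at line %d", col,
                   bad[1] + 1L))
    traj[[col]] <- as.numeric(traj[[col]])
  }
  traj$frame <- as.integer(traj$frame)
  dup <- duplicated(traj[, c("fly_id", "frame")])
  if (any(dup))
    stop(sprintf("duplicate (fly, frame) row at line %d: fly %s frame %d",
                 which(dup)[1] + 1L, traj$fly_id[which(dup)[1]],
                 traj$frame[which(dup)[1]]))
  if (check_units) {
    span <- max(sqrt(traj$x_mm^2 + traj$y_mm^2))
    if (span < 0.15 * config$radius)
      stop(sprintf(
        "positions span only %.1f mm in a %g mm arena; positions must be in mm (cm values are not rescaled)",
        span, config$radius))
  }
  validate_trajectories(traj, config)
}

#' Write a trajectory table
#'
#' @param traj A trajectory table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  traj <- traj[order(traj$fly_id, traj$frame),
               c("frame", "fly_id", "t_s", "x_mm", "y_mm")]
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Trikinetics-style monitor file
#'
#' Parses the tab-delimited monitor dialect: each row is a 1-min reading
#' with a reading index, date (`d mon yy`), time (`HH:MM:SS`), a status
#' code, then 32 channel counts. Rows whose status code is not 1 indicate a
#' reader error and are rejected with a report; the remaining rows must form
#' an uninterrupted 1-min sequence over whole days. No imputation is
#' performed.
#'
#' @param path Path to the monitor file.
#' @param phases Named list mapping phase names to day numbers.
#' @param lights_on Clock time (`"HH:MM"`) of lights-on, used to place the
#'   12:12 cycle.
#' @return A list of 32 [activity_record()] objects; the number of rejected
#'   rows is attached as attribute `n_rejected`.
#' @export
read_dam <- function(path, phases = list(baseline = 1:3, activation = 4:5,
                                         recovery = 6:7),
                     lights_on = "08:00") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 36))
    stop(sprintf("line %d has %d tab-separated fields; expected 36 (index, date, time, status, 32 channels)",
                 which(n_fields != 36)[1], n_fields[n_fields != 36][1]))
  mat <- do.call(rbind, fields)
  status <- as.integer(mat[, 4])
  rejected <- status != 1L
  if (any(rejected))
    message(sprintf("rejected %d row(s) with non-ok status codes: %s",
                    sum(rejected),
                    paste(unique(status[rejected]), collapse = ", ")))
  mat <- mat[!rejected, , drop = FALSE]
  dt <- as.POSIXct(paste(mat[, 2], mat[, 3]), format = "%d %b %y %H:%M:%S",
                   tz = "UTC")
  if (anyNA(dt)) stop("unparseable date/time at data row ", which(is.na(dt))[1])
  steps <- as.numeric(diff(dt), units = "mins")
  if (any(steps != 1)) {
    i <- which(steps != 1)[1]
    stop(sprintf("non-contiguous timestamps between %s and %s (missing or out-of-order minutes)",
                 format(dt[i]), format(dt[i + 1])))
  }
  counts <- apply(mat[, 5:36, drop = FALSE], 2, as.integer)
  if (anyNA(counts)) stop("malformed count field in monitor file")
  lo <- as.integer(strsplit(lights_on, ":")[[1]])
  lights_on_min <- lo[1] * 60 + lo[2]
  first_min <- as.integer(format(dt[1], "%H")) * 60 +
    as.integer(format(dt[1], "%M"))
  # day 1 starts at the first sample; lights-on offset is relative to it
  offset <- (lights_on_min - first_min) %% 1440
  recs <- lapply(seq_len(32), function(ch) {
    activity_record(channel = sprintf("ch%02d", ch), counts = counts[, ch],
                    phases = phases, lights_on_minute = offset)
  })
  attr(recs, "n_rejected") <- sum(rejected)
  recs
}

#' Read a simplified activity CSV
#'
#' Reads the simplified dialect `channel,day,minute,count` (minute is
#' 1-based within day) into activity records.
#'
#' @param path Path to the CSV.
#' @param phases Named list mapping phase names to day numbers.
#' @param lights_on_minute Minute of day at which lights turn on.
#' @return A list of [activity_record()] objects, one per channel.
#' @export
read_dam_csv <- function(path, phases = list(baseline = 1:3,
                                             activation = 4:5,
                                             recovery = 6:7),
                         lights_on_minute = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("channel", "day", "minute", "count")
  if (!identical(names(d), expected))
    stop("header must be exactly: ", paste(expected, collapse = ","))
  lapply(split(d, d$channel), function(ch) {
    ch <- ch[order(ch$day, ch$minute), , drop = FALSE]
    idx <- (ch$day - 1L) * 1440L + ch$minute
    n_days <- max(ch$day)
    counts <- rep(NA_integer_, n_days * 1440L)
    if (anyDuplicated(idx))
      stop("duplicate (day, minute) rows for channel ", ch$channel[1])
    counts[idx] <- ch$count
    activity_record(channel = ch$channel[1], counts = counts,
                    phases = phases, lights_on_minute = lights_on_minute)
  })
}

#' Write a simplified activity CSV
#'
#' @param records A list of [activity_record()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dam_csv <- function(records, path) {
  rows <- lapply(records, function(rec) {
    data.frame(channel = rec$channel,
               day = (seq_along(rec$counts) - 1L) %/% 1440L + 1L,
               minute = (seq_along(rec$counts) - 1L) %% 1440L + 1L,
               count = rec$counts)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run a simulate-then-analyze arena pipeline
#'
#' Executes the arena stages end to end from a single configuration:
#' simulates (or reads) a cohort, computes the preference time series, the
#' light preference index, choice-zone events, exit fractions, choice
#' probability and state-conditioned kinematics, and writes all tables
#' (CSV), a summary (JSON) and a provenance record (JSON: configuration
#' echo, seed, package version, input checksums) into the output directory.
#' Identical seeds give byte-identical summaries.
#'
#' @param config A list with elements `outdir` (required), `seed`, and
#'   either `simulate` (a list of [agent_params()] arguments) or
#'   `trajectories` (path to a trajectory CSV); optional `arena` (list of
#'   [arena_config()] arguments) and filter settings `angle_min`,
#'   `angle_max`, `min_prior_mm`.
#' @return The summary list, invisibly; files are written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outdir))
  arena <- do.call(arena_config, config$arena %||% list())
  schedule <- default_schedule()
  input_checksum <- NULL
  if (!is.null(config$trajectories)) {
    if (!file.exists(config$trajectories))
      stop("input file not found: ", config$trajectories)
    input_checksum <- unname(tools::md5sum(config$trajectories))
    traj <- read_trajectories(config$trajectories, arena)
  } else {
    sim_args <- config$simulate %||% list()
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    params <- do.call(agent_params, sim_args)
    traj <- simulate_arena_cohort(params, arena, schedule)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  series <- preference_timeseries(traj, schedule, arena)
  lpi <- light_preference_index(series, schedule)
  events <- segment_choice_events(traj, arena, schedule)
  filt <- filter_choice_events(events,
                               angle_min = config$angle_min %||% 45,
                               angle_max = config$angle_max %||% 135,
                               min_prior_mm = config$min_prior_mm %||% 5)
  fractions <- exit_fractions(filt$events)
  cp <- if (nrow(filt$events) > 0) choice_probability(filt$events) else NA_real_
  kin <- state_conditioned_kinematics(traj, schedule, arena)

  write_trajectories(traj, file.path(config$outdir, "trajectories.csv"))
  utils::write.csv(series, file.path(config$outdir, "preference.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(events, file.path(config$outdir, "choice_events.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    light_preference = lpi,
    choice = list(n_events_opened = unname(attr(events, "counts")[["opened"]]),
                  n_retained = nrow(filt$events),
                  removed = as.list(filt$removed),
                  exit_fractions = fractions,
                  choice_probability = cp),
    kinematics = kin
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(
    package = "flyvalence",
    version = as.character(utils::packageVersion("flyvalence")),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    input_md5 = input_checksum,
    stage_counts = list(events = as.list(attr(events, "counts")),
                        removed = as.list(filt$removed))
  )
  jsonlite::write_json(provenance, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
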