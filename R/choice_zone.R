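#' Segment choice-zone visits into classified events
#'
#' Scans each fly's trajectory for visits to the choice zone (the +/- 5 mm
#' band around a light on/off border). An event opens at the first frame
#' inside the band, entered from a contiguous out-of-band frame, and closes
#' at the first subsequent out-of-band frame. The entry and exit sides are
#' the illumination states of the positions just before entry and just after
#' exit; an event is a `crossing` when they differ and a `turnaround` when
#' they match.
#'
#' Events are censored (listed, but excluded from fractions) when the entry
#' or exit is lost to a tracking gap or the end of the track, when the event
#' straddles an illumination-epoch boundary, when it falls in a dark (or
#' uniformly lit) epoch where the lit/unlit side labels are undefined, or
#' when it begins within `early_entry_censor` seconds of a light-on epoch
#' start (the light state the fly is responding to is not yet stable).
#'
#' Each event also carries the entry angle (the angle between the approach
#' heading, estimated over `config$heading_window` frames before entry, and
#' the entry border line: degrees in (0, 180) for flies facing the border
#' with 90 = perpendicular approach, and in (180, 360) for flies moving away
#' from it, which can only enter through the ends of the band and are
#' removed by the facing filter) and the net displacement over the second
#' before entry. Events lacking the pre-entry frames needed for these are
#' flagged unfilterable via `NA`.
#'
#' @param traj A trajectory table (one or many flies).
#' @param config An [arena_config()].
#' @param schedule An [illumination_schedule()].
#' @param early_entry_censor Seconds after a light-on epoch start during
#'   which new entries are censored.
#' @return A data frame of events with columns `fly_id`, `t_entry`,
#'   `entry_border`, `entry_side`, `entry_angle_deg`, `prior_disp_mm`,
#'   `t_exit`, `exit_side`, `outcome` (`crossing`/`turnaround`/`censored`)
#'   and `censor_reason`; attributes `counts` (events opened/censored by
#'   reason) and `n_always_inside` (flies whose whole track lay in the band).
#' @export
segment_choice_events <- function(traj, config = arena_config(),
                                  schedule = default_schedule(),
                                  early_entry_censor = 1) {
  traj <- validate_trajectories(traj, config)
  span <- schedule_span(schedule)
  traj <- traj[traj$t_s >= span[1] - 1e-9 & traj$t_s <= span[2] + 1e-9, ,
               drop = FALSE]
  out <- list()
  n_always_inside <- 0L
  fps <- config$frame_rate
  hw <- config$heading_window

  for (fly in unique(traj$fly_id)) {
    d <- traj[traj$fly_id == fly, , drop = FALSE]
    inz <- in_choice_zone(d$x_mm, d$y_mm, config, d$fly_id, d$frame)
    if (all(inz)) {
      n_always_inside <- n_always_inside + 1L
      next
    }
    # split into contiguous-frame segments; zone runs never span a gap
    seg_id <- cumsum(c(1L, as.integer(diff(d$frame) != 1L)))
    for (seg in split(seq_len(nrow(d)), seg_id)) {
      r <- rle(inz[seg])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- seg[starts[k]]              # first in-zone frame
        i1 <- seg[ends[k]]                # last in-zone frame
        has_entry <- starts[k] > 1L
        has_exit <- ends[k] < length(seg)
        ip <- if (has_entry) seg[starts[k] - 1L] else NA_integer_
        ix <- if (has_exit) seg[ends[k] + 1L] else NA_integer_

        entry_side <- exit_side <- NA_character_
        censor <- NA_character_
        if (!has_entry) {
          censor <- "entry_gap"
        } else {
          ep_entry <- epoch_at(d$t_s[ip], schedule)
          lit_set <- schedule$lit[[ep_entry]]
          entry_side <- illumination_state(d$x_mm[ip], d$y_mm[ip], d$t_s[ip],
                                           schedule, config)
          if (!has_exit) {
            censor <- "track_loss"
          } else {
            exit_side <- illumination_state(d$x_mm[ix], d$y_mm[ix], d$t_s[ix],
                                            schedule, config)
            if (epoch_at(d$t_s[ix], schedule) != ep_entry) {
              censor <- "epoch_boundary"
            } else if (length(lit_set) == 0) {
              censor <- "dark_epoch"
            } else if (length(lit_set) == 4) {
              censor <- "uniform_light"
            } else if (d$t_s[ip] - schedule$t_start[ep_entry] <
                       early_entry_censor) {
              censor <- "early_epoch"
            }
          }
        }

        angle <- NA_real_
        prior <- NA_real_
        if (has_entry) {
          ih <- i0 - hw
          if (ih >= seg[1]) {
            bd <- border_distance(d$x_mm[i0], d$y_mm[i0], config)
            perp <- if (bd$border == "vertical") d$x_mm else d$y_mm
            side_sign <- sign(perp[i0])
            if (side_sign == 0) side_sign <- sign(perp[ip])
            angle <- heading_border_angle(
              d$x_mm[i0] - d$x_mm[ih], d$y_mm[i0] - d$y_mm[ih], bd$border,
              side_sign)
          }
          ipre <- i0 - as.integer(round(fps))
          if (ipre >= seg[1]) {
            prior <- sqrt((d$x_mm[i0] - d$x_mm[ipre])^2 +
                          (d$y_mm[i0] - d$y_mm[ipre])^2)
          }
        }

        outcome <- if (!is.na(censor)) "censored"
                   else if (exit_side != entry_side) "crossing"
                   else "turnaround"
        out[[length(out) + 1L]] <- data.frame(
          fly_id = fly,
          t_entry = d$t_s[i0],
          entry_border = if (has_entry)
            border_distance(d$x_mm[i0], d$y_mm[i0], config)$border
            else NA_character_,
          entry_side = entry_side,
          entry_angle_deg = angle,
          prior_disp_mm = prior,
          t_exit = if (has_exit) d$t_s[ix] else NA_real_,
          exit_side = exit_side,
          outcome = outcome,
          censor_reason = censor,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  events <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    fly_id = character(0), t_entry = numeric(0), entry_border = character(0),
    entry_side = character(0), entry_angle_deg = numeric(0),
    prior_disp_mm = numeric(0), t_exit = numeric(0), exit_side = character(0),
    outcome = character(0), censor_reason = character(0),
    stringsAsFactors = FALSE)
  if (n_always_inside > 0)
    warning(sprintf("%d track(s) lay entirely inside the choice zone; no events",
                    n_always_inside))
  attr(events, "counts") <- c(
    opened = nrow(events),
    censored = sum(events$outcome == "censored"),
    table(factor(events$censor_reason,
                 levels = c("entry_gap", "track_loss", "epoch_boundary",
                            "dark_epoch", "uniform_light", "early_epoch")))
  )
  attr(events, "n_always_inside") <- n_always_inside
  events
}

# direction-aware angle between a heading vector and a border line.
# `side_sign` is the sign of the coordinate perpendicular to the border at
# the entry point (which side of the border the fly is on). Headings toward
# the border map to (0, 180) with 90 = perpendicular approach; headings away
# from it (entries through the ends of the band) map to (180, 360).
heading_border_angle <- function(dx, dy, border, side_sign) {
  if ((dx == 0 && dy == 0) || side_sign == 0) return(NA_real_)
  if (border == "vertical") {   # border line x = 0, direction (0, 1)
    along <- dy
    toward <- -side_sign * dx
  } else {                      # border line y = 0, direction (1, 0)
    along <- dx
    toward <- -side_sign * dy
  }
  (atan2(toward, along) * 180 / pi) %% 360
}

#' Entry angle of a choice-zone event
#'
#' Recomputes the angle between the pre-entry heading (the displacement
#' vector from `config$heading_window` frames before entry to the entry
#' frame) and the entry border line. Angles in (0, 180) mean the fly faced
#' the border (90 = perpendicular approach); angles in (180, 360) mean it
#' was moving away from the border.
#'
#' @param traj The trajectory table the event came from.
#' @param event A one-row event data frame (from [segment_choice_events()]).
#' @param config An [arena_config()].
#' @return Angle in degrees, or `NA` if the pre-entry frames are missing.
#' @export
entry_angle <- function(traj, event, config = arena_config()) {
  stopifnot(nrow(event) == 1)
  d <- traj[traj$fly_id == event$fly_id, , drop = FALSE]
  d <- d[order(d$frame), , drop = FALSE]
  f_entry <- as.integer(round(event$t_entry * config$frame_rate))
  i0 <- match(f_entry, d$frame)
  ih <- match(f_entry - config$heading_window, d$frame)
  if (is.na(i0) || is.na(ih)) return(NA_real_)
  if (!all((d$frame[ih:i0] - d$frame[ih]) == 0:(i0 - ih))) return(NA_real_)
  bd <- border_distance(d$x_mm[i0], d$y_mm[i0], config)
  perp <- if (bd$border == "vertical") d$x_mm else d$y_mm
  side_sign <- sign(perp[i0])
  if (side_sign == 0 && i0 > 1) side_sign <- sign(perp[i0 - 1])
  heading_border_angle(d$x_mm[i0] - d$x_mm[ih], d$y_mm[i0] - d$y_mm[ih],
                       bd$border, side_sign)
}

#' Filter choice-zone events by approach geometry and prior movement
#'
#' Retains events whose entry angle lies within `[angle_min, angle_max]`
#' (the fly was facing the border) and whose net displacement in the second
#' before entry exceeded `min_prior_mm` (the fly was moving, strictly more
#' than the threshold). Censored and unfilterable events are removed first.
#'
#' @param events Events from [segment_choice_events()].
#' @param angle_min,angle_max Entry-angle bounds in degrees.
#' @param min_prior_mm Strict lower bound on pre-entry displacement (mm).
#' @return A list with `events` (the retained rows) and `removed`, a named
#'   count of events dropped by each criterion (applied in the order
#'   censored, unfilterable, angle, displacement).
#' @export
filter_choice_events <- function(events, angle_min = 45, angle_max = 135,
                                 min_prior_mm = 5) {
  cens <- events$outcome == "censored"
  e <- events[!cens, , drop = FALSE]
  unf <- is.na(e$entry_angle_deg) | is.na(e$prior_disp_mm)
  e2 <- e[!unf, , drop = FALSE]
  bad_angle <- e2$entry_angle_deg < angle_min | e2$entry_angle_deg > angle_max
  e3 <- e2[!bad_angle, , drop = FALSE]
  bad_disp <- !(e3$prior_disp_mm > min_prior_mm)
  e4 <- e3[!bad_disp, , drop = FALSE]
  rownames(e4) <- NULL
  list(events = e4,
       removed = c(censored = sum(cens), unfilterable = sum(unf),
                   angle = sum(bad_angle), displacement = sum(bad_disp)))
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Exit-to-light fractions by entry side
#'
#' For events entering from the dark side, the fraction that exit to the
#' illuminated side (crossings into the light); for events entering from the
#' lit side, the fraction that also exit to the illuminated side (turning
#' around back into the light). Confidence intervals are Wilson score
#' intervals.
#'
#' @param events Retained events (the `events` element of
#'   [filter_choice_events()]).
#' @param conf_level Confidence level for the Wilson intervals.
#' @return A data frame with one row per entry side (`unlit`, `lit`):
#'   `n`, `n_exit_lit`, `fraction`, `ci_lower`, `ci_upper`. Sides with no
#'   events get `NA` fractions.
#' @export
exit_fractions <- function(events, conf_level = 0.95) {
  res <- lapply(c("unlit", "lit"), function(side) {
    e <- events[events$entry_side == side, , drop = FALSE]
    n <- nrow(e)
    if (n == 0)
      return(data.frame(entry_side = side, n = 0L, n_exit_lit = NA_integer_,
                        fraction = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    k <- sum(e$exit_side == "lit")
    ci <- wilson_interval(k, n, conf_level)
    data.frame(entry_side = side, n = n, n_exit_lit = k, fraction = k / n,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  })
  do.call(rbind, res)
}

#' Choice probability
#'
#' The fraction of retained choice-zone events that exit to the illuminated
#' side, irrespective of the side of entry: (dark-entry exits to light +
#' lit-entry exits to light) / all retained events.
#'
#' @param events Retained events (from [filter_choice_events()]).
#' @return A number in [0, 1].
#' @export
choice_probability <- function(events) {
  if (nrow(events) == 0) stop("no retained choice-zone events")
  mean(events$exit_side == "lit")
}

#' Frame-wise walking speed and angular speed
#'
#' Speed is the distance moved between successive frames times the frame
#' rate. The heading is the direction of the frame-to-frame displacement;
#' angular speed is the absolute heading change between successive steps
#' (wrapped to [0, 180] degrees) times the frame rate. Frames following a
#' tracking gap are undefined, as is the heading (and hence angular speed)
#' whenever the speed falls below `config$min_heading_speed`, where the
#' direction of a jittering, nearly stationary fly is ill-posed.
#'
#' @param traj A trajectory table (one or many flies).
#' @param config An [arena_config()].
#' @return A data frame `fly_id`, `frame`, `t_s`, `x_mm`, `y_mm`, `speed`
#'   (mm/s), `angular_speed` (deg/s), with `NA` where undefined.
#' @export
kinematics <- function(traj, config = arena_config()) {
  traj <- validate_trajectories(traj, config)
  fps <- config$frame_rate
  res <- lapply(split(traj, traj$fly_id), function(d) {
    n <- nrow(d)
    speed <- rep(NA_real_, n)
    angular <- rep(NA_real_, n)
    if (n >= 2) {
      contig <- c(FALSE, diff(d$frame) == 1L)
      dx <- c(NA, diff(d$x_mm))
      dy <- c(NA, diff(d$y_mm))
      step <- sqrt(dx^2 + dy^2)
      speed[contig] <- step[contig] * fps
      heading <- atan2(dy, dx) * 180 / pi
      heading[!contig | is.na(speed) | speed < config$min_heading_speed] <- NA
      dh <- c(NA, diff(heading))
      dh <- abs(((dh + 180) %% 360) - 180)
      ok <- contig & c(FALSE, contig[-n]) & !is.na(dh)
      angular[ok] <- dh[ok] * fps
    }
    data.frame(fly_id = d$fly_id, frame = d$frame, t_s = d$t_s,
               x_mm = d$x_mm, y_mm = d$y_mm, speed = speed,
               angular_speed = angular)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Kinematics conditioned on quadrant illumination state
#'
#' Pools frame-level speeds and angular speeds by whether the fly's current
#' quadrant is lit or unlit, restricted to light-on epochs, and returns the
#' per-video means together with the lit-minus-unlit changes and the
#' lit/unlit speed ratio. One row is returned per call; the video (cohort)
#' is the replicate unit.
#'
#' @param traj A trajectory table.
#' @param schedule An [illumination_schedule()].
#' @param config An [arena_config()].
#' @return A one-row data frame with means, changes, the speed ratio and the
#'   frame counts behind each state; states never occupied yield `NA`.
#' @export
state_conditioned_kinematics <- function(traj, schedule = default_schedule(),
                                         config = arena_config()) {
  kin <- kinematics(traj, config)
  span <- schedule_span(schedule)
  kin <- kin[kin$t_s >= span[1] - 1e-9 & kin$t_s <= span[2] + 1e-9, ,
             drop = FALSE]
  lit_sets <- lit_quadrants_at(kin$t_s, schedule)
  in_lit_epoch <- lengths(lit_sets) > 0 & lengths(lit_sets) < 4
  kin <- kin[in_lit_epoch, , drop = FALSE]
  if (nrow(kin) == 0) stop("no frames within light-on epochs")
  state <- illumination_state(kin$x_mm, kin$y_mm, kin$t_s, schedule, config)
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sp_lit <- mean_or_na(kin$speed[state == "lit"])
  sp_unlit <- mean_or_na(kin$speed[state == "unlit"])
  as_lit <- mean_or_na(kin$angular_speed[state == "lit"])
  as_unlit <- mean_or_na(kin$angular_speed[state == "unlit"])
  data.frame(
    mean_speed_lit = sp_lit, mean_speed_unlit = sp_unlit,
    speed_change = sp_lit - sp_unlit, speed_ratio = sp_lit / sp_unlit,
    mean_angular_speed_lit = as_lit, mean_angular_speed_unlit = as_unlit,
    angular_speed_change = as_lit - as_unlit,
    n_frames_lit = sum(state == "lit"),
    n_frames_unlit = sum(state == "unlit")
  )
}
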