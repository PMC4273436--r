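#' Arena configuration
#'
#' Describes the geometry and illumination optics of a four-quadrant circular
#' arena. The arena is centered at the origin with the two light on/off
#' borders fixed along the coordinate axes, so the distance of a point to the
#' nearest border is `min(|x|, |y|)`. Units are millimetres, seconds and
#' microwatts per square millimetre throughout.
#'
#' @param radius Arena radius in mm (a 10 cm arena has radius 50).
#' @param choice_halfwidth Half-width of the choice zone in mm; the zone is
#'   the band within `choice_halfwidth` of a border.
#' @param center_exclusion_radius Radius in mm of the central disk excluded
#'   from choice-zone membership. Near the center the two borders intersect
#'   (and the arena has an air hole), so "which border" is ill-defined there.
#' @param frame_rate Video frame rate in Hz.
#' @param intensity_max Plateau irradiance on the lit side, in uW/mm^2.
#' @param intensity_min_at_border Irradiance at the light on/off border.
#' @param gradient_length Length in mm of the linear intensity ramp extending
#'   from the border into the lit side.
#' @param out_of_bounds_tolerance Tracker jitter allowance in mm: points up
#'   to this far outside `radius` are accepted, anything further is an error
#'   (this catches cm-vs-mm unit mistakes loudly).
#' @param heading_window Number of frames before a choice-zone entry used to
#'   estimate the entry heading vector.
#' @param min_heading_speed Speed in mm/s below which the heading (and hence
#'   angular speed) is treated as undefined.
#' @return An object of class `arena_config`.
#' @examples
#' cfg <- arena_config()
#' assign_quadrant(10, 10, cfg)
#' @export
arena_config <- function(radius = 50,
                         choice_halfwidth = 5,
                         center_exclusion_radius = 10,
                         frame_rate = 30,
                         intensity_max = 34,
                         intensity_min_at_border = 3,
                         gradient_length = 10,
                         out_of_bounds_tolerance = 1,
                         heading_window = 3,
                         min_heading_speed = 0.5) {
  stopifnot(
    radius > 0,
    choice_halfwidth > 0, choice_halfwidth < radius,
    center_exclusion_radius >= choice_halfwidth,
    frame_rate > 0,
    intensity_max >= intensity_min_at_border,
    intensity_min_at_border >= 0,
    gradient_length > 0,
    out_of_bounds_tolerance >= 0,
    heading_window >= 1,
    min_heading_speed >= 0
  )
  structure(
    list(
      radius = radius,
      choice_halfwidth = choice_halfwidth,
      center_exclusion_radius = center_exclusion_radius,
      frame_rate = frame_rate,
      intensity_max = intensity_max,
      intensity_min_at_border = intensity_min_at_border,
      gradient_length = gradient_length,
      out_of_bounds_tolerance = out_of_bounds_tolerance,
      heading_window = heading_window,
      min_heading_speed = min_heading_speed
    ),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config>\n")
  cat(sprintf("  radius: %g mm, choice zone: +/- %g mm, center exclusion: %g mm\n",
              x$radius, x$choice_halfwidth, x$center_exclusion_radius))
  cat(sprintf("  frame rate: %g Hz\n", x$frame_rate))
  cat(sprintf("  intensity: %g -> %g uW/mm^2 over %g mm ramp\n",
              x$intensity_min_at_border, x$intensity_max, x$gradient_length))
  invisible(x)
}

QUADRANTS <- c("Q1", "Q2", "Q3", "Q4")

#' Illumination schedule
#'
#' An ordered, contiguous set of epochs, each illuminating a subset of the
#' four quadrants. Valid lit sets are the empty set, one of the two diagonal
#' pairs (`Q2`/`Q3` or `Q1`/`Q4`), or all four quadrants.
#'
#' @param epochs A data frame with numeric columns `t_start`, `t_end` (s) and
#'   a list column `lit` of character vectors naming the lit quadrants.
#' @return An object of class `illumination_schedule`.
#' @seealso [default_schedule()] for the standard 120 s protocol.
#' @export
illumination_schedule <- function(epochs) {
  stopifnot(is.data.frame(epochs),
            all(c("t_start", "t_end", "lit") %in% names(epochs)),
            nrow(epochs) >= 1)
  epochs <- epochs[order(epochs$t_start), , drop = FALSE]
  rownames(epochs) <- NULL
  if (!is.list(epochs$lit)) epochs$lit <- as.list(epochs$lit)
  if (any(epochs$t_start >= epochs$t_end))
    stop("every epoch must have t_start < t_end")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$t_start[-1] - epochs$t_end[-nrow(epochs)]) > 1e-9))
    stop("epochs must be contiguous and non-overlapping")
  diagonal_pairs <- list(c("Q2", "Q3"), c("Q1", "Q4"))
  for (lit in epochs$lit) {
    lit <- sort(unique(as.character(lit)))
    ok <- length(lit) == 0 ||
      identical(lit, sort(QUADRANTS)) ||
      any(vapply(diagonal_pairs, function(p) identical(lit, sort(p)), logical(1)))
    if (!ok)
      stop("lit set must be empty, a diagonal pair (Q2&Q3 or Q1&Q4), or all quadrants")
  }
  structure(list(t_start = epochs$t_start, t_end = epochs$t_end,
                 lit = lapply(epochs$lit, as.character)),
            class = "illumination_schedule")
}

#' Standard two-epoch illumination protocol
#'
#' The default 120 s protocol: darkness for 0-30 s, quadrants Q2 and Q3 lit
#' for 30-60 s, darkness for 60-90 s, quadrants Q1 and Q4 lit for 90-120 s.
#'
#' @return An `illumination_schedule`.
#' @export
default_schedule <- function() {
  illumination_schedule(data.frame(
    t_start = c(0, 30, 60, 90),
    t_end = c(30, 60, 90, 120),
    lit = I(list(character(0), c("Q2", "Q3"), character(0), c("Q1", "Q4")))
  ))
}

#' @export
print.illumination_schedule <- function(x, ...) {
  cat("<illumination_schedule>\n")
  for (i in seq_along(x$t_start)) {
    lit <- if (length(x$lit[[i]]) == 0) "none" else paste(x$lit[[i]], collapse = ",")
    cat(sprintf("  %6.1f - %6.1f s : %s\n", x$t_start[i], x$t_end[i], lit))
  }
  invisible(x)
}

#' Total time span of a schedule
#' @param schedule An `illumination_schedule`.
#' @return Numeric vector `c(start, end)` in seconds.
#' @export
schedule_span <- function(schedule) {
  c(schedule$t_start[1], schedule$t_end[length(schedule$t_end)])
}

#' Index of the epoch containing each time point
#'
#' Times on an epoch boundary belong to the later epoch; the final end time
#' belongs to the last epoch.
#'
#' @param t Numeric vector of times (s).
#' @param schedule An `illumination_schedule`.
#' @return Integer vector of epoch indices.
#' @export
epoch_at <- function(t, schedule) {
  span <- schedule_span(schedule)
  if (any(t < span[1] - 1e-9 | t > span[2] + 1e-9))
    stop(sprintf("time outside schedule span [%g, %g] s", span[1], span[2]))
  idx <- findInterval(pmin(pmax(t, span[1]), span[2]), schedule$t_start)
  pmin(idx, length(schedule$t_start))
}

#' Quadrants lit at each time point
#' @inheritParams epoch_at
#' @return A list of character vectors, one per element of `t`.
#' @export
lit_quadrants_at <- function(t, schedule) {
  schedule$lit[epoch_at(t, schedule)]
}

check_in_arena <- function(x, y, config, fly_id = NULL, frame = NULL) {
  r <- sqrt(x^2 + y^2)
  bad <- which(r > config$radius + config$out_of_bounds_tolerance)
  if (length(bad) > 0) {
    i <- bad[1]
    who <- if (!is.null(fly_id)) sprintf(" (fly %s, frame %s)",
                                         as.character(fly_id[i]),
                                         as.character(frame[i])) else ""
    stop(sprintf(
      "point (%.2f, %.2f) lies %.2f mm outside the arena radius %g mm%s; check units (positions must be in mm)",
      x[i], y[i], r[i] - config$radius, config$radius, who))
  }
  invisible(TRUE)
}

#' Assign points to arena quadrants
#'
#' Quadrants are labelled so that `Q2` and `Q3` form one diagonal pair and
#' `Q1` and `Q4` the other: `Q1` is the (+x, +y) quadrant, `Q2` (-x, +y),
#' `Q3` (+x, -y) and `Q4` (-x, -y). Points lying exactly on an axis are
#' assigned to the positive side (the quadrant reached by an infinitesimal
#' +x/+y perturbation), which makes the assignment deterministic.
#'
#' @param x,y Numeric vectors of coordinates in mm.
#' @param config An [arena_config()].
#' @param fly_id,frame Optional identifiers used in out-of-bounds messages.
#' @return Character vector of quadrant ids (`"Q1"`..`"Q4"`).
#' @export
assign_quadrant <- function(x, y, config = arena_config(),
                            fly_id = NULL, frame = NULL) {
  check_in_arena(x, y, config, fly_id, frame)
  px <- x >= 0
  py <- y >= 0
  ifelse(px & py, "Q1",
         ifelse(!px & py, "Q2",
                ifelse(px & !py, "Q3", "Q4")))
}

#' Distance to the nearest light on/off border
#'
#' The two borders lie along the coordinate axes; the distance of a point to
#' the nearest border is `min(|x|, |y|)`. The "vertical" border is the line
#' x = 0 (along the y-axis) and the "horizontal" border the line y = 0; ties
#' resolve to the vertical border.
#'
#' @inheritParams assign_quadrant
#' @return A data frame with columns `distance` (mm) and `border`
#'   (`"vertical"` or `"horizontal"`).
#' @export
border_distance <- function(x, y, config = arena_config(),
                            fly_id = NULL, frame = NULL) {
  check_in_arena(x, y, config, fly_id, frame)
  data.frame(
    distance = pmin(abs(x), abs(y)),
    border = ifelse(abs(x) <= abs(y), "vertical", "horizontal")
  )
}

#' Choice-zone membership
#'
#' A point is in the choice zone when it lies within `choice_halfwidth` of a
#' border and outside the central exclusion disk (where the two borders
#' intersect and border identity is ambiguous).
#'
#' @inheritParams assign_quadrant
#' @return Logical vector.
#' @export
in_choice_zone <- function(x, y, config = arena_config(),
                           fly_id = NULL, frame = NULL) {
  bd <- border_distance(x, y, config, fly_id, frame)
  bd$distance <= config$choice_halfwidth &
    sqrt(x^2 + y^2) >= config$center_exclusion_radius
}

#' Illumination state of points at given times
#'
#' @inheritParams assign_quadrant
#' @param t Numeric vector of times (s), recycled against `x`/`y`.
#' @param schedule An [illumination_schedule()].
#' @return Character vector, `"lit"` or `"unlit"`.
#' @export
illumination_state <- function(x, y, t, schedule = default_schedule(),
                               config = arena_config(),
                               fly_id = NULL, frame = NULL) {
  n <- max(length(x), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  q <- assign_quadrant(x, y, config, fly_id, frame)
  lit_sets <- lit_quadrants_at(t, schedule)
  lit <- vapply(seq_len(n), function(i) q[i] %in% lit_sets[[i]], logical(1))
  ifelse(lit, "lit", "unlit")
}

#' Light intensity experienced at points and times
#'
#' Irradiance is 0 on unlit quadrants and during dark epochs. On a lit
#' quadrant it ramps linearly from `intensity_min_at_border` at the border to
#' `intensity_max` at `gradient_length` from the border, and is constant at
#' the plateau beyond that.
#'
#' @inheritParams illumination_state
#' @return Numeric vector of irradiance in uW/mm^2.
#' @export
light_intensity <- function(x, y, t, schedule = default_schedule(),
                            config = arena_config(),
                            fly_id = NULL, frame = NULL) {
  n <- max(length(x), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  state <- illumination_state(x, y, t, schedule, config, fly_id, frame)
  d <- pmin(border_distance(x, y, config)$distance, config$gradient_length)
  ramp <- config$intensity_min_at_border +
    (config$intensity_max - config$intensity_min_at_border) *
    d / config$gradient_length
  ifelse(state == "lit", ramp, 0)
}

#' Validate a trajectory table
#'
#' Checks that a trajectory table has the required columns
#' (`frame`, `fly_id`, `t_s`, `x_mm`, `y_mm`), that frames are strictly
#' increasing and unique per fly, that times are consistent with the frame
#' rate, and that all positions are inside the arena (within the jitter
#' tolerance). Gaps in the frame sequence are permitted and reported.
#'
#' @param traj A data frame of tracked positions.
#' @param config An [arena_config()].
#' @return The validated table (sorted by fly then frame), invisibly carrying
#'   a `gaps` attribute: a data frame of missing-frame counts per fly.
#' @export
validate_trajectories <- function(traj, config = arena_config()) {
  req <- c("frame", "fly_id", "t_s", "x_mm", "y_mm")
  missing_cols <- setdiff(req, names(traj))
  if (length(missing_cols) > 0)
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(traj) == 0) stop("trajectory table is empty")
  traj <- traj[order(traj$fly_id, traj$frame), , drop = FALSE]
  rownames(traj) <- NULL
  dup <- duplicated(traj[, c("fly_id", "frame")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate frame %d for fly %s", traj$frame[i],
                 as.character(traj$fly_id[i])))
  }
  bad_t <- abs(traj$t_s - traj$frame / config$frame_rate) > 0.5 / config$frame_rate
  if (any(bad_t)) {
    i <- which(bad_t)[1]
    stop(sprintf("t_s (%g) inconsistent with frame/frame_rate (%g) at fly %s frame %d",
                 traj$t_s[i], traj$frame[i] / config$frame_rate,
                 as.character(traj$fly_id[i]), traj$frame[i]))
  }
  check_in_arena(traj$x_mm, traj$y_mm, config, traj$fly_id, traj$frame)
  gaps <- do.call(rbind, lapply(split(traj$frame, traj$fly_id), function(f) {
    data.frame(n_frames = length(f),
               n_missing = (max(f) - min(f) + 1) - length(f))
  }))
  gaps$fly_id <- rownames(gaps)
  rownames(gaps) <- NULL
  attr(traj, "gaps") <- gaps[, c("fly_id", "n_frames", "n_missing")]
  traj
}
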