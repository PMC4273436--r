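#' Parameters for the arena cohort simulator
#'
#' Describes a cohort of correlated-random-walk agent flies in the
#' four-quadrant arena. Each fly draws a per-frame speed from a truncated
#' normal, diffuses its heading, smoothly avoids the wall, and makes one
#' Bernoulli choice decision per choice-zone entry: with probability
#' `|valence|` the entry is resolved toward the preferred side (the dark
#' side for negative valence, the lit side for positive). A fly headed
#' toward the non-preferred side then executes a smooth ~180 degree
#' reversal over about 0.3 s (so the turn-around probability is
#' `max(0, -valence)` toward the light and `max(0, valence)` toward the
#' dark); a fly already headed toward the preferred side commits to the
#' crossing, holding its heading until it leaves the zone. Valence
#' therefore acts on border choice only; the lit multipliers separately
#' scale steady-state speed and heading diffusion in illuminated quadrants
#' (to emulate sensory-driven kinematic phenotypes).
#'
#' Defaults reproduce the standard assay: ~20 flies, 120 s protocol at
#' 30 fps. If `valence` has several elements (co-activated effector
#' combinations) they are summed and clipped to \[-1, 1\].
#'
#' @param n_flies Number of flies in the cohort.
#' @param duration Protocol duration in seconds.
#' @param frame_rate Sampling rate in Hz.
#' @param mean_speed,speed_sd Walking-speed distribution, mm/s.
#' @param heading_diffusion Heading diffusion coefficient, deg^2/s.
#' @param wall_avoidance_range Distance from the wall (mm) at which inward
#'   steering begins.
#' @param valence Behavioral valence in \[-1, 1\]; negative = light-aversive.
#' @param lit_speed_multiplier,lit_turn_multiplier Multipliers applied to
#'   speed and heading diffusion while in a lit quadrant.
#' @param turnaround_duration Nominal duration of a border reversal, s.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(n_flies = 20, duration = 120, frame_rate = 30,
                         mean_speed = 10, speed_sd = 3,
                         heading_diffusion = 3000, wall_avoidance_range = 5,
                         valence = 0, lit_speed_multiplier = 1,
                         lit_turn_multiplier = 1, turnaround_duration = 0.3,
                         seed = 1) {
  valence <- max(-1, min(1, sum(valence)))
  stopifnot(n_flies >= 1, duration > 0, frame_rate > 0,
            mean_speed > 0, speed_sd >= 0, heading_diffusion >= 0,
            wall_avoidance_range > 0, abs(valence) <= 1,
            lit_speed_multiplier > 0, lit_turn_multiplier > 0,
            turnaround_duration > 0, length(seed) == 1, !is.na(seed))
  structure(as.list(environment()), class = "agent_params")
}

# fast lit-quadrant membership for the simulator (zero counts as positive)
quadrant_is_lit <- function(x, y, lit_set) {
  if (length(lit_set) == 0) return(rep(FALSE, length(x)))
  if (length(lit_set) == 4) return(rep(TRUE, length(x)))
  opposite_signs <- xor(x >= 0, y >= 0)  # quadrants Q2 (-,+) and Q3 (+,-)
  if (setequal(lit_set, c("Q2", "Q3"))) opposite_signs else !opposite_signs
}

#' Simulate an arena cohort
#'
#' Runs the correlated-random-walk agent model described in
#' [agent_params()] under an illumination schedule and returns a trajectory
#' table in the standard format, ready for [preference_timeseries()] and
#' [segment_choice_events()]. Simulated positions never leave the arena.
#'
#' @param params An [agent_params()].
#' @param config An [arena_config()].
#' @param schedule An [illumination_schedule()].
#' @return A trajectory table `frame`, `fly_id`, `t_s`, `x_mm`, `y_mm`.
#' @export
simulate_arena_cohort <- function(params = agent_params(),
                                  config = arena_config(),
                                  schedule = default_schedule()) {
  stopifnot(inherits(params, "agent_params"))
  set.seed(params$seed)
  n <- params$n_flies
  fps <- params$frame_rate
  dt <- 1 / fps
  n_frames <- as.integer(round(params$duration * fps)) + 1L
  n_ta <- as.integer(round(params$turnaround_duration * fps))
  sd_frame <- sqrt(params$heading_diffusion * dt)
  rad <- config$radius

  # initial state: uniform over the disk (95% of radius), random headings
  r0 <- 0.95 * rad * sqrt(stats::runif(n))
  th0 <- stats::runif(n, 0, 360)
  x <- r0 * cospi(th0 / 180)
  y <- r0 * sinpi(th0 / 180)
  heading <- stats::runif(n, 0, 360)
  ta_left <- integer(n)
  ta_dir <- integer(n)
  committed <- logical(n)
  prev_in_zone <- in_zone_fast(x, y, config)

  X <- matrix(NA_real_, nrow = n_frames, ncol = n)
  Y <- matrix(NA_real_, nrow = n_frames, ncol = n)
  X[1, ] <- x; Y[1, ] <- y

  span <- schedule_span(schedule)
  for (f in seq_len(n_frames - 1L)) {
    t_new <- f * dt
    lit_set <- if (t_new <= span[2]) lit_quadrants_at(min(t_new, span[2]),
                                                      schedule)[[1]]
               else character(0)
    lit <- quadrant_is_lit(x, y, lit_set)

    speed <- pmax(0, stats::rnorm(n, params$mean_speed, params$speed_sd))
    speed[lit] <- speed[lit] * params$lit_speed_multiplier

    turning <- ta_left > 0L
    free <- !turning & !committed
    diff_sd <- sd_frame * ifelse(lit, sqrt(params$lit_turn_multiplier), 1)
    heading[free] <- heading[free] + stats::rnorm(sum(free), 0, diff_sd[free])
    heading[committed & !turning] <-
      heading[committed & !turning] +
      stats::rnorm(sum(committed & !turning), 0, 2)
    if (any(turning)) {
      heading[turning] <- heading[turning] +
        ta_dir[turning] * (180 / n_ta) + stats::rnorm(sum(turning), 0, 5)
      ta_left[turning] <- ta_left[turning] - 1L
    }

    # smooth inward steering near the wall
    r <- sqrt(x^2 + y^2)
    near <- free & r > rad - params$wall_avoidance_range
    if (any(near)) {
      inward <- atan2(-y[near], -x[near]) * 180 / pi
      delta <- ((inward - heading[near] + 180) %% 360) - 180
      pen <- (r[near] - (rad - params$wall_avoidance_range)) /
        params$wall_avoidance_range
      heading[near] <- heading[near] + delta * 0.5 * pen
    }

    x_new <- x + speed * dt * cospi(heading / 180)
    y_new <- y + speed * dt * sinpi(heading / 180)
    r_new <- sqrt(x_new^2 + y_new^2)
    out <- r_new > rad - 0.5
    if (any(out)) {
      scale <- (rad - 0.5) / r_new[out]
      x_new[out] <- x_new[out] * scale
      y_new[out] <- y_new[out] * scale
      heading[out] <- atan2(-y_new[out], -x_new[out]) * 180 / pi +
        stats::rnorm(sum(out), 0, 20)
      ta_left[out] <- 0L
      committed[out] <- FALSE
    }

    # one choice decision per zone entry, only under two-quadrant light
    in_zone <- in_zone_fast(x_new, y_new, config)
    committed[!in_zone] <- FALSE
    entered <- in_zone & !prev_in_zone & ta_left == 0L
    v <- params$valence
    if (any(entered) && length(lit_set) == 2 && v != 0) {
      # decisions apply only to flies actually approaching the border
      # (entries through the ends of the band face no light choice)
      ex <- x_new[entered]; ey <- y_new[entered]
      vertical <- abs(ex) <= abs(ey)
      approaching <- ifelse(
        vertical,
        -sign(ex) * cospi(heading[entered] / 180) > 0,
        -sign(ey) * sinpi(heading[entered] / 180) > 0)
      from_lit <- quadrant_is_lit(x[entered], y[entered], lit_set)
      # entering from the lit side means heading toward the dark side;
      # the preferred side is dark for v < 0, light for v > 0
      toward_pref <- if (v < 0) from_lit else !from_lit
      act <- approaching & stats::runif(sum(entered)) < abs(v)
      idx_turn <- which(entered)[act & !toward_pref]
      if (length(idx_turn) > 0) {
        ta_left[idx_turn] <- n_ta +
          sample(-2:2, length(idx_turn), replace = TRUE)
        ta_dir[idx_turn] <- sample(c(-1L, 1L), length(idx_turn),
                                   replace = TRUE)
      }
      committed[which(entered)[act & toward_pref]] <- TRUE
    }
    prev_in_zone <- in_zone
    x <- x_new; y <- y_new
    X[f + 1L, ] <- x; Y[f + 1L, ] <- y
  }

  frames <- rep(seq_len(n_frames) - 1L, times = n)
  data.frame(
    frame = frames,
    fly_id = rep(sprintf("fly%02d", seq_len(n)), each = n_frames),
    t_s = frames / fps,
    x_mm = as.vector(X),
    y_mm = as.vector(Y)
  )
}

in_zone_fast <- function(x, y, config) {
  pmin(abs(x), abs(y)) <= config$choice_halfwidth &
    sqrt(x^2 + y^2) >= config$center_exclusion_radius
}

#' Parameters for the activity-monitor simulator
#'
#' Each channel is a per-minute two-state (wake/sleep) Markov chain with
#' light- and phase-dependent transition probabilities; beam-crossing counts
#' are 0 while asleep and Poisson while awake (awake zeros occur, as in real
#' monitors). During activation days the wake-to-sleep onset probabilities
#' are replaced so that the stationary sleep occupancy changes by
#' `target_sleep_change` percent while bout lengths (the sleep-to-wake
#' probabilities) are preserved; recovery days revert to baseline.
#'
#' @param n_channels Number of monitor channels (flies).
#' @param phases Named list mapping phase names to day numbers.
#' @param p_sleep_onset Baseline per-minute wake-to-sleep probabilities,
#'   named `light` and `dark`.
#' @param p_wake Per-minute sleep-to-wake probabilities, named `light` and
#'   `dark` (these set mean bout length and are phase-invariant).
#' @param target_sleep_change Percent change in sleep imposed during
#'   activation days (e.g. -40); `NULL` leaves activation at baseline.
#' @param mean_waking_counts Mean beam crossings per awake minute.
#' @param lights_on_minute Minute of day at which lights turn on.
#' @param seed Integer seed.
#' @return An object of class `dam_params`.
#' @export
dam_params <- function(n_channels = 32,
                       phases = list(baseline = 1:3, activation = 4:5,
                                     recovery = 6:7),
                       p_sleep_onset = c(light = 1 / 30, dark = 0.15),
                       p_wake = c(light = 0.10, dark = 0.05),
                       target_sleep_change = NULL,
                       mean_waking_counts = 2,
                       lights_on_minute = 0,
                       seed = 1) {
  stopifnot(n_channels >= 1,
            all(c("light", "dark") %in% names(p_sleep_onset)),
            all(c("light", "dark") %in% names(p_wake)),
            all(p_sleep_onset > 0 & p_sleep_onset < 1),
            all(p_wake > 0 & p_wake < 1),
            mean_waking_counts >= 0)
  activation_p_sleep_onset <- p_sleep_onset
  if (!is.null(target_sleep_change)) {
    for (ph in c("light", "dark")) {
      pi_base <- p_sleep_onset[[ph]] / (p_sleep_onset[[ph]] + p_wake[[ph]])
      pi_act <- min(0.999, max(0.001, pi_base * (1 + target_sleep_change / 100)))
      activation_p_sleep_onset[[ph]] <- pi_act * p_wake[[ph]] / (1 - pi_act)
    }
  }
  structure(list(n_channels = n_channels, phases = phases,
                 p_sleep_onset = p_sleep_onset, p_wake = p_wake,
                 activation_p_sleep_onset = activation_p_sleep_onset,
                 target_sleep_change = target_sleep_change,
                 mean_waking_counts = mean_waking_counts,
                 lights_on_minute = lights_on_minute, seed = seed),
            class = "dam_params")
}

#' Simulate activity-monitor records
#'
#' @param params A [dam_params()].
#' @return A list of [activity_record()] objects, one per channel.
#' @export
simulate_dam <- function(params = dam_params()) {
  stopifnot(inherits(params, "dam_params"))
  set.seed(params$seed)
  days <- sort(unlist(params$phases, use.names = FALSE))
  n_days <- length(days)
  n_min <- n_days * 1440L
  nc <- params$n_channels

  phase_by_day <- rep(NA_character_, n_days)
  for (ph in names(params$phases)) phase_by_day[params$phases[[ph]]] <- ph
  minute_of_day <- (seq_len(n_min) - 1L) %% 1440L
  is_light <- ((minute_of_day - params$lights_on_minute) %% 1440L) < 720L
  day_of_min <- (seq_len(n_min) - 1L) %/% 1440L + 1L
  is_activation <- phase_by_day[day_of_min] == "activation"

  lp <- ifelse(is_light, "light", "dark")
  p_on <- ifelse(is_activation,
                 params$activation_p_sleep_onset[lp],
                 params$p_sleep_onset[lp])
  p_off <- params$p_wake[lp]

  # initial state from the baseline stationary distribution
  pi0 <- params$p_sleep_onset[lp[1]] /
    (params$p_sleep_onset[lp[1]] + params$p_wake[lp[1]])
  asleep <- matrix(FALSE, nrow = n_min, ncol = nc)
  asleep[1, ] <- stats::runif(nc) < pi0
  for (m in 2:n_min) {
    prev <- asleep[m - 1L, ]
    u <- stats::runif(nc)
    asleep[m, ] <- ifelse(prev, u >= p_off[m], u < p_on[m])
  }

  lapply(seq_len(nc), function(ch) {
    counts <- integer(n_min)
    awake <- !asleep[, ch]
    counts[awake] <- stats::rpois(sum(awake), params$mean_waking_counts)
    activity_record(channel = sprintf("ch%02d", ch), counts = counts,
                    phases = params$phases,
                    lights_on_minute = params$lights_on_minute)
  })
}

#' Parameters for the reciprocal T-maze simulator
#'
#' Each fly in a group chooses the bias-favored arm with probability
#' `0.5 + bias/2 -/+ delta/2`, the sign of the learning term depending on
#' whether the group's CS+ was the favored arm (punished flies avoid their
#' CS+). Group counts are binomial draws. The constraint
#' `|bias| + |delta| <= 1` keeps the choice probabilities in \[0, 1\].
#'
#' @param n_per_group Flies per trained group.
#' @param bias Innate bias toward the first arm, in \[-1, 1\].
#' @param delta Learning effect, in \[-1, 1\].
#' @param arms Names of the two arms; the bias favors the first.
#' @param seed Integer seed.
#' @return An object of class `tmaze_params`.
#' @export
tmaze_params <- function(n_per_group = 40, bias = 0, delta = 0,
                         arms = c("OCT", "MCH"), seed = 1) {
  stopifnot(n_per_group >= 1, abs(bias) + abs(delta) <= 1,
            length(arms) == 2)
  structure(list(n_per_group = n_per_group, bias = bias, delta = delta,
                 arms = arms, seed = seed),
            class = "tmaze_params")
}

#' Simulate a reciprocal two-choice experiment
#'
#' @param params A [tmaze_params()].
#' @return A count table in the [tmaze_pi()] input format: columns `group`,
#'   `cs_plus`, `arm`, `count`, with group 1 trained against the first arm
#'   and group 2 against the second.
#' @export
simulate_tmaze <- function(params = tmaze_params()) {
  stopifnot(inherits(params, "tmaze_params"))
  set.seed(params$seed)
  a <- params$arms
  n <- params$n_per_group
  # probability of choosing the favored (first) arm
  p1 <- 0.5 + params$bias / 2 - params$delta / 2  # CS+ = favored arm
  p2 <- 0.5 + params$bias / 2 + params$delta / 2  # CS+ = other arm
  k1 <- stats::rbinom(1, n, p1)
  k2 <- stats::rbinom(1, n, p2)
  data.frame(
    group = rep(c(1L, 2L), each = 2),
    cs_plus = rep(a, each = 2),
    arm = rep(a, times = 2),
    count = c(k1, n - k1, k2, n - k2),
    stringsAsFactors = FALSE
  )
}
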