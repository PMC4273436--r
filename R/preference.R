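#' Per-frame quadrant preference time series
#'
#' For every frame in the tracked span, counts the flies in each quadrant and
#' computes the quadrant preference `(N_Q2&Q3 - N_Q1&Q4) / N` and, during
#' epochs with lit quadrants, the light preference `(N_lit - N_unlit) / N`.
#' Frames with no tracked fly are kept in the output with `NA` preferences
#' (undefined, not zero); flies untracked in a frame simply reduce `N` for
#' that frame.
#'
#' @param traj A trajectory table (see [validate_trajectories()]).
#' @param schedule An [illumination_schedule()].
#' @param config An [arena_config()].
#' @return A data frame with columns `t_s`, `q_pref`, `light_pref`,
#'   `n_flies`, one row per frame of the tracked span.
#' @export
preference_timeseries <- function(traj, schedule = default_schedule(),
                                  config = arena_config()) {
  traj <- validate_trajectories(traj, config)
  span <- schedule_span(schedule)
  keep <- traj$t_s >= span[1] - 1e-9 & traj$t_s <= span[2] + 1e-9
  traj <- traj[keep, , drop = FALSE]
  if (nrow(traj) == 0) stop("no trajectory samples within the schedule span")

  q <- assign_quadrant(traj$x_mm, traj$y_mm, config, traj$fly_id, traj$frame)
  frames <- seq(min(traj$frame), max(traj$frame))
  t_s <- frames / config$frame_rate
  fidx <- match(traj$frame, frames)

  n_flies <- tabulate(fidx, nbins = length(frames))
  n_q23 <- tabulate(fidx[q %in% c("Q2", "Q3")], nbins = length(frames))
  q_pref <- ifelse(n_flies > 0, (2 * n_q23 - n_flies) / n_flies, NA_real_)

  lit_sets <- lit_quadrants_at(t_s, schedule)
  has_lit <- lengths(lit_sets) > 0 & lengths(lit_sets) < 4
  lit_fly <- vapply(seq_len(nrow(traj)),
                    function(i) q[i] %in% lit_sets[[fidx[i]]], logical(1))
  n_lit <- tabulate(fidx[lit_fly], nbins = length(frames))
  light_pref <- ifelse(has_lit & n_flies > 0,
                       (2 * n_lit - n_flies) / n_flies, NA_real_)

  data.frame(t_s = t_s, q_pref = q_pref, light_pref = light_pref,
             n_flies = n_flies)
}

#' Light preference index
#'
#' Averages the light preference over the final seconds of each light-on
#' epoch (default: the last 5 s, i.e. 55-60 s and 115-120 s of the standard
#' protocol) and combines the per-window means into a single preference
#' index, the unweighted mean of the window means. Positive values indicate
#' attraction to the illuminated quadrants.
#'
#' @param series Output of [preference_timeseries()].
#' @param schedule The [illumination_schedule()] the series was computed
#'   under.
#' @param window Length in seconds of the terminal averaging window of each
#'   light-on epoch.
#' @return A list with elements `window_pis` (one mean per light-on epoch)
#'   and `pi` (their mean).
#' @export
light_preference_index <- function(series, schedule = default_schedule(),
                                   window = 5) {
  lit_epochs <- which(lengths(schedule$lit) > 0)
  if (length(lit_epochs) == 0)
    stop("schedule contains no light-on epochs")
  window_pis <- vapply(lit_epochs, function(e) {
    t0 <- schedule$t_end[e] - window
    t1 <- schedule$t_end[e]
    sel <- series$t_s >= t0 - 1e-9 & series$t_s <= t1 + 1e-9
    vals <- series$light_pref[sel]
    if (!any(sel) || all(is.na(vals)))
      stop(sprintf("series does not cover the window %g-%g s", t0, t1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  list(window_pis = window_pis, pi = mean(window_pis))
}
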