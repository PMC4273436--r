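#' Analyze one arena cohort end to end
#'
#' Convenience wrapper running the full arena analysis on a single cohort
#' (one video): preference time series and light preference index,
#' choice-zone segmentation, filtering, exit fractions, choice probability
#' and state-conditioned kinematics.
#'
#' @param traj A trajectory table.
#' @param config An [arena_config()].
#' @param schedule An [illumination_schedule()].
#' @param angle_min,angle_max,min_prior_mm Filter settings passed to
#'   [filter_choice_events()].
#' @return A list with `pi` (light preference index), `window_pis`,
#'   `choice_probability`, `exit_fractions`, `n_events`, `removed`, and
#'   `kinematics` (the one-row data frame of
#'   [state_conditioned_kinematics()]).
#' @export
analyze_arena_cohort <- function(traj, config = arena_config(),
                                 schedule = default_schedule(),
                                 angle_min = 45, angle_max = 135,
                                 min_prior_mm = 5) {
  lpi <- light_preference_index(preference_timeseries(traj, schedule, config),
                                schedule)
  events <- segment_choice_events(traj, config, schedule)
  filt <- filter_choice_events(events, angle_min, angle_max, min_prior_mm)
  list(
    pi = lpi$pi,
    window_pis = lpi$window_pis,
    choice_probability = if (nrow(filt$events) > 0)
      choice_probability(filt$events) else NA_real_,
    exit_fractions = exit_fractions(filt$events),
    n_events = nrow(filt$events),
    removed = filt$removed,
    kinematics = state_conditioned_kinematics(traj, schedule, config)
  )
}

#' Simulate and analyze a panel of valence genotypes
#'
#' Runs replicate simulated cohorts across a grid of valence values (a
#' synthetic genotype panel) and collects the per-cohort valence metrics:
#' light preference index, choice probability, dark-entry exit-to-light
#' fraction, and the lit-minus-unlit kinematic changes. This is the
#' workhorse behind the package's calibration checks relating preference to
#' border choice and to kinematics.
#'
#' @param valences Numeric vector of valence values.
#' @param n_replicates Replicate cohorts per valence.
#' @param base_seed Integer; cohort seeds are derived deterministically from
#'   it, the valence index and the replicate number.
#' @param params_fn Function mapping `(valence, seed)` to an
#'   [agent_params()]; replace to alter cohort parameters (e.g. lit
#'   multipliers).
#' @param config An [arena_config()].
#' @param schedule An [illumination_schedule()].
#' @return A data frame with one row per cohort: `valence`, `replicate`,
#'   `seed`, `pi`, `choice_prob`, `dark_exit_lit`, `lit_exit_lit`,
#'   `n_dark`, `n_dark_exit_lit`, `n_lit`, `n_lit_exit_lit`,
#'   `speed_change`, `speed_ratio`, `angular_speed_change`, `n_events`.
#' @export
simulate_valence_panel <- function(valences, n_replicates = 10,
                                   base_seed = 1,
                                   params_fn = function(valence, seed)
                                     agent_params(valence = valence,
                                                  seed = seed),
                                   config = arena_config(),
                                   schedule = default_schedule()) {
  rows <- list()
  for (vi in seq_along(valences)) {
    for (r in seq_len(n_replicates)) {
      seed <- base_seed + 1000L * vi + r
      traj <- simulate_arena_cohort(params_fn(valences[vi], seed), config,
                                    schedule)
      res <- analyze_arena_cohort(traj, config, schedule)
      ef <- res$exit_fractions
      dark <- ef[ef$entry_side == "unlit", ]
      litr <- ef[ef$entry_side == "lit", ]
      rows[[length(rows) + 1L]] <- data.frame(
        valence = valences[vi], replicate = r, seed = seed,
        pi = res$pi, choice_prob = res$choice_probability,
        dark_exit_lit = dark$fraction, lit_exit_lit = litr$fraction,
        n_dark = dark$n, n_dark_exit_lit = dark$n_exit_lit,
        n_lit = litr$n, n_lit_exit_lit = litr$n_exit_lit,
        speed_change = res$kinematics$speed_change,
        speed_ratio = res$kinematics$speed_ratio,
        angular_speed_change = res$kinematics$angular_speed_change,
        n_events = res$n_events
      )
    }
  }
  do.call(rbind, rows)
}
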