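#' Performance index from a reciprocal two-choice count table
#'
#' In a reciprocal design two groups are trained with swapped conditioned
#' stimuli (CS+). Each group's preference index is the normalized count
#' difference between the two test arms, signed so that positive values mean
#' behavior consistent with training: avoidance of the CS+ after punishment,
#' approach to the CS+ after reward. The performance index is the mean of
#' the two group indices, which cancels any innate stimulus bias shared by
#' the groups.
#'
#' @param counts A data frame with columns `group`, `cs_plus` (the arm name
#'   that was reinforced for that group), `arm` and `count`; exactly two
#'   groups with swapped `cs_plus`.
#' @param reinforcement `"punishment"` (default) or `"reward"`; controls the
#'   sign convention.
#' @return A list with `group_indices` (named per group) and `pi`.
#' @examples
#' tab <- data.frame(group = c(1, 1, 2, 2),
#'                   cs_plus = c("OCT", "OCT", "MCH", "MCH"),
#'                   arm = c("OCT", "MCH", "OCT", "MCH"),
#'                   count = c(10, 30, 30, 10))
#' tmaze_pi(tab)$pi  # 0.5
#' @export
tmaze_pi <- function(counts, reinforcement = c("punishment", "reward")) {
  reinforcement <- match.arg(reinforcement)
  stopifnot(all(c("group", "cs_plus", "arm", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  groups <- unique(counts$group)
  if (length(groups) != 2)
    stop("a reciprocal experiment needs exactly two groups")
  idx <- vapply(groups, function(g) {
    d <- counts[counts$group == g, , drop = FALSE]
    csp <- unique(d$cs_plus)
    if (length(csp) != 1) stop("each group must have a single cs_plus")
    n_cs <- sum(d$count[d$arm == csp])
    n_other <- sum(d$count[d$arm != csp])
    total <- n_cs + n_other
    if (total == 0) stop(sprintf("group %s has zero total count", g))
    raw <- (n_other - n_cs) / total   # positive = avoided the CS+
    if (reinforcement == "punishment") raw else -raw
  }, numeric(1))
  names(idx) <- as.character(groups)
  if (length(unique(counts$cs_plus)) != 2)
    stop("the two groups must have swapped cs_plus assignments")
  list(group_indices = idx, pi = mean(idx))
}

#' Performance index from per-frame arm counts
#'
#' Scores a reciprocal two-choice test monitored by videography: each
#' group's index is the time average, over the final `window` seconds of the
#' `period`-second choice phase, of the per-frame signed index
#' `(N_other - N_cs+) / N` (for punishment), then the group indices are
#' averaged as in [tmaze_pi()].
#'
#' @param series A data frame with columns `group`, `cs_plus`, `t_s`,
#'   `arm`, `count`: per-frame counts in each arm for each group.
#' @param period Length of the choice period in seconds.
#' @param window Length of the terminal scoring window in seconds.
#' @param reinforcement `"punishment"` or `"reward"`.
#' @return A list with `group_indices` and `pi`.
#' @export
tmaze_series_pi <- function(series, period = 120, window = 10,
                            reinforcement = c("punishment", "reward")) {
  reinforcement <- match.arg(reinforcement)
  stopifnot(all(c("group", "cs_plus", "t_s", "arm", "count") %in% names(series)))
  if (max(series$t_s) < period - 1e-9)
    stop(sprintf("series ends at %g s; the final %g s window of the %g s period is not covered",
                 max(series$t_s), window, period))
  sel <- series$t_s > period - window - 1e-9 & series$t_s <= period + 1e-9
  series <- series[sel, , drop = FALSE]
  groups <- unique(series$group)
  idx <- vapply(groups, function(g) {
    d <- series[series$group == g, , drop = FALSE]
    csp <- unique(d$cs_plus)
    if (length(csp) != 1) stop("each group must have a single cs_plus")
    per_frame <- vapply(split(d, d$t_s), function(fr) {
      n_cs <- sum(fr$count[fr$arm == csp])
      n_other <- sum(fr$count[fr$arm != csp])
      tot <- n_cs + n_other
      if (tot == 0) return(NA_real_)
      (n_other - n_cs) / tot
    }, numeric(1))
    raw <- mean(per_frame, na.rm = TRUE)
    if (reinforcement == "punishment") raw else -raw
  }, numeric(1))
  names(idx) <- as.character(groups)
  list(group_indices = idx, pi = mean(idx))
}

#' Visual-conditioning performance index from color-count series
#'
#' Scores a reciprocal color-conditioning test in which per-frame counts of
#' flies on blue versus green quadrants are recorded (typically at 1 frame/s
#' over a 90 s test). Each group's preference is the mean per-frame
#' `(N_blue - N_green) / N`; the group index is signed so that positive
#' means avoidance of the shocked color, and the performance index is the
#' mean of the two reciprocal group indices. Setting
#' `convention = "difference"` instead returns the difference between the
#' two groups' raw preferences (the sum of the signed indices), an
#' alternative convention that is exactly twice the mean.
#'
#' @param series A data frame with columns `group`, `cs_plus` (`"blue"` or
#'   `"green"`), `t_s`, `n_blue`, `n_green`.
#' @param convention `"mean"` (default) or `"difference"`.
#' @return A list with `group_indices` and `pi`.
#' @export
visual_pi <- function(series, convention = c("mean", "difference")) {
  convention <- match.arg(convention)
  stopifnot(all(c("group", "cs_plus", "t_s", "n_blue", "n_green") %in%
                  names(series)))
  groups <- unique(series$group)
  if (length(groups) != 2)
    stop("a reciprocal experiment needs exactly two groups")
  idx <- vapply(groups, function(g) {
    d <- series[series$group == g, , drop = FALSE]
    csp <- unique(d$cs_plus)
    if (length(csp) != 1 || !csp %in% c("blue", "green"))
      stop("each group needs a single cs_plus of 'blue' or 'green'")
    tot <- d$n_blue + d$n_green
    if (all(tot == 0)) stop(sprintf("group %s has zero total count", g))
    pref <- mean(ifelse(tot > 0, (d$n_blue - d$n_green) / tot, NA_real_),
                 na.rm = TRUE)
    if (csp == "blue") -pref else pref  # positive = avoided shocked color
  }, numeric(1))
  names(idx) <- as.character(groups)
  pi_val <- switch(convention, mean = mean(idx), difference = sum(idx))
  list(group_indices = idx, pi = pi_val)
}

#' Conditioned preference index from reciprocal Y-maze trials
#'
#' Each trial's preference index is `(n_odor - n_air) / (n_odor + n_air)`;
#' the conditioned preference index is the average over the reciprocal
#' trials.
#'
#' @param odor_count,air_count Equal-length vectors of per-trial fly counts
#'   in the odor and air arms (the reciprocal trials of one experiment).
#' @return A list with `trial_indices` and `pi`.
#' @export
ymaze_pi <- function(odor_count, air_count) {
  stopifnot(length(odor_count) == length(air_count),
            all(odor_count >= 0), all(air_count >= 0))
  tot <- odor_count + air_count
  if (any(tot == 0)) stop("every trial needs a non-zero total count")
  idx <- (odor_count - air_count) / tot
  list(trial_indices = idx, pi = mean(idx))
}
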