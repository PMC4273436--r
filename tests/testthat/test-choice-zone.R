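cfg <- arena_config()
sch <- default_schedule()

# straight horizontal path at y = 30 crossing the vertical border, with
# enough lead-in for the angle and prior-displacement filters
straight_cross <- function(x0 = -20, x1 = 20, step = 0.4, t0 = 35) {
  x <- seq(x0, x1, by = step)
  make_traj(x, rep(30, length(x)), frame0 = as.integer(t0 * 30))
}

test_that("a straight border crossing yields one crossing event", {
  ev <- segment_choice_events(straight_cross(), cfg, sch)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$outcome, "crossing")
  expect_equal(ev$entry_side, "lit")     # Q2 lit at 35 s, entering from x < 0
  expect_equal(ev$exit_side, "unlit")
  expect_equal(ev$entry_border, "vertical")
  # timing: opens at first |x| <= 5 frame, closes at first |x| > 5 frame
  x <- seq(-20, 20, by = 0.4)
  expect_equal(ev$t_entry, (35 * 30 + which(abs(x) <= 5)[1] - 1) / 30)
})

test_that("a reversal inside the zone yields one turnaround event", {
  x <- c(seq(-20, -1, by = 0.4), seq(-1.4, -20, by = -0.4))
  tr <- make_traj(x, rep(30, length(x)), frame0 = 35L * 30L)
  ev <- segment_choice_events(tr, cfg, sch)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$outcome, "turnaround")
  expect_equal(ev$entry_side, ev$exit_side)
})

test_that("events spanning an epoch boundary or a dark epoch are censored", {
  # crossing that straddles the 60 s light-off transition
  ev <- segment_choice_events(straight_cross(t0 = 58.2), cfg, sch)
  expect_true(all(ev$outcome == "censored"))
  expect_true("epoch_boundary" %in% ev$censor_reason)
  # same geometry during the 0-30 s dark epoch
  ev <- segment_choice_events(straight_cross(t0 = 10), cfg, sch)
  expect_equal(ev$censor_reason, "dark_epoch")
  # entry within the first second of a light-on epoch
  ev <- segment_choice_events(straight_cross(-6, 8, t0 = 30.2), cfg, sch)
  expect_equal(ev$censor_reason, "early_epoch")
})

test_that("tracking gaps censor the event they interrupt", {
  tr <- straight_cross()
  inside <- which(abs(tr$x_mm) <= 5)
  tr <- tr[-inside[5], ]  # drop one in-zone frame
  ev <- segment_choice_events(tr, cfg, sch)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$censor_reason, c("track_loss", "entry_gap"))
})

test_that("segmentation matches the per-frame state-machine scan on random walks", {
  for (s in 1:3) {
    traj <- simulate_arena_cohort(
      agent_params(n_flies = 10, valence = c(-0.6, 0, 0.6)[s], seed = 30 + s),
      cfg, sch)
    expect_events_match_oracle(traj, cfg, sch)
  }
})

test_that("entry angle recovers constructed approach geometries", {
  # perpendicular approach to the vertical border from the left
  ev <- segment_choice_events(straight_cross(), cfg, sch)
  expect_equal(ev$entry_angle_deg, 90, tolerance = 1e-6)
  # 45 degree approach: heading (+1, -1)/sqrt(2) toward the horizontal
  # border from above
  n <- 80
  x <- seq(20, by = 0.3, length.out = n)
  y <- seq(18, by = -0.3, length.out = n)
  ev <- segment_choice_events(make_traj(x, y, frame0 = 35L * 30L), cfg, sch)
  expect_equal(ev$entry_angle_deg[1], 45, tolerance = 1)
  # parallel motion along the band (entered via the inner end of the band)
  x <- seq(8, 30, by = 0.4)
  tr <- make_traj(x, rep(4, length(x)), frame0 = 35L * 30L)
  ev <- segment_choice_events(tr, cfg, sch)
  expect_equal(ev$entry_angle_deg[1] %% 180, 0, tolerance = 1e-6)
  # receding entries (via the band end, moving away) map to (180, 360)
  x <- seq(4.0, by = 0.02, length.out = 60)
  y <- seq(7.5, by = 0.3, length.out = 60)
  ev <- segment_choice_events(make_traj(x, y, frame0 = 35L * 30L), cfg, sch)
  expect_true(ev$entry_angle_deg[1] > 180)
})

test_that("the facing and prior-movement filters apply the stated bounds", {
  base <- data.frame(
    fly_id = "f1", t_entry = 40, entry_border = "vertical",
    entry_side = "unlit", entry_angle_deg = 90, prior_disp_mm = 8,
    t_exit = 41, exit_side = "lit", outcome = "crossing",
    censor_reason = NA_character_, stringsAsFactors = FALSE)
  ev <- rbind(base, base, base, base, base)
  ev$entry_angle_deg <- c(90, 30, 45, 135, 136)
  ev$prior_disp_mm <- c(8, 8, 8, 8, 8)
  f <- filter_choice_events(ev)
  expect_equal(nrow(f$events), 3)  # 90, 45 and 135 kept; bounds inclusive
  expect_equal(unname(f$removed[["angle"]]), 2)

  ev2 <- rbind(base, base, base)
  ev2$prior_disp_mm <- c(5.0, 5.01, 8)
  f2 <- filter_choice_events(ev2)
  expect_equal(nrow(f2$events), 2)  # exactly 5 mm fails the strict bound
  expect_equal(unname(f2$removed[["displacement"]]), 1)

  ev3 <- rbind(base, base)
  ev3$outcome[2] <- "censored"
  expect_equal(unname(filter_choice_events(ev3)$removed[["censored"]]), 1)
})

test_that("exit fractions carry Wilson intervals and handle empty sides", {
  ev <- data.frame(
    entry_side = rep("unlit", 10),
    exit_side = c(rep("lit", 5), rep("unlit", 5)))
  fr <- exit_fractions(ev)
  dark <- fr[fr$entry_side == "unlit", ]
  expect_equal(dark$fraction, 0.5)
  ref <- prop.test(5, 10, correct = FALSE)$conf.int
  expect_equal(dark$ci_lower, ref[1], tolerance = 1e-8)
  expect_equal(dark$ci_upper, ref[2], tolerance = 1e-8)
  expect_true(is.na(fr$fraction[fr$entry_side == "lit"]))
  all_lit <- data.frame(entry_side = rep("unlit", 8),
                        exit_side = rep("lit", 8))
  expect_equal(exit_fractions(all_lit)$fraction[1], 1)
})

test_that("choice probability pools exits to light over all retained events", {
  ev <- data.frame(
    entry_side = c(rep("unlit", 10), rep("lit", 10)),
    exit_side = c(rep("lit", 3), rep("unlit", 7),
                  rep("lit", 2), rep("unlit", 8)))
  expect_equal(choice_probability(ev), 0.25)
  # complement identity
  expect_equal(choice_probability(ev), 1 - mean(ev$exit_side == "unlit"))
  expect_error(choice_probability(ev[0, ]), "no retained")
})

test_that("speed and angular speed follow the successive-frame definition", {
  # straight motion at 0.5 mm/frame
  tr <- make_traj(seq(0, 10, by = 0.5), rep(20, 21))
  k <- kinematics(tr, cfg)
  expect_equal(k$speed[-1], rep(15, 20))
  expect_equal(k$angular_speed[-(1:2)], rep(0, 19))
  expect_true(is.na(k$speed[1]))
  # stationary fly: zero speed, heading (and angular speed) undefined
  tr <- make_traj(rep(10, 10), rep(20, 10))
  k <- kinematics(tr, cfg)
  expect_equal(k$speed[-1], rep(0, 9))
  expect_true(all(is.na(k$angular_speed)))
})

test_that("angular speed on a circular path matches the analytic turn rate", {
  omega <- 90  # deg/s
  tt <- seq(0, 3, by = 1 / 30)
  tr <- make_traj(20 * cospi(omega * tt / 180), 20 * sinpi(omega * tt / 180))
  k <- kinematics(tr, cfg)
  expect_equal(mean(k$angular_speed, na.rm = TRUE), omega, tolerance = 0.02)
  expect_equal(mean(k$speed, na.rm = TRUE), 20 * omega * pi / 180,
               tolerance = 0.02)
})

test_that("frames after a tracking gap have undefined kinematics", {
  tr <- make_traj(seq(0, 10, by = 0.5), rep(20, 21))
  tr <- tr[-10, ]
  k <- kinematics(tr, cfg)
  expect_true(is.na(k$speed[10]))        # frame following the gap
  expect_true(is.na(k$angular_speed[11]))
})

test_that("state-conditioned kinematics split frames by quadrant light state", {
  # light-independent kinematics: lit and unlit means agree
  traj <- simulate_arena_cohort(agent_params(seed = 35), cfg, sch)
  sk <- state_conditioned_kinematics(traj, sch, cfg)
  expect_equal(sk$speed_ratio, 1, tolerance = 0.05)
  # imposed 1.5x lit speed is recovered
  traj <- simulate_arena_cohort(
    agent_params(lit_speed_multiplier = 1.5, seed = 36), cfg, sch)
  sk <- state_conditioned_kinematics(traj, sch, cfg)
  expect_equal(sk$speed_ratio, 1.5, tolerance = 0.05)
  # a fly that never occupies a lit quadrant has undefined lit means
  one <- make_traj(seq(20, 26, by = 0.2), rep(20, 31),
                   frame0 = 35L * 30L)  # stays in Q1, unlit at 35 s
  sk <- state_conditioned_kinematics(one, sch, cfg)
  expect_true(is.na(sk$mean_speed_lit))
  expect_true(is.na(sk$speed_change))
})
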