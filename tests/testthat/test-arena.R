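cfg <- arena_config()

test_that("quadrant assignment follows the diagonal-pair sign convention", {
  expect_equal(assign_quadrant(10, 10, cfg), "Q1")
  expect_equal(assign_quadrant(-10, 10, cfg), "Q2")
  expect_equal(assign_quadrant(10, -10, cfg), "Q3")
  expect_equal(assign_quadrant(-10, -10, cfg), "Q4")
  # Q2 & Q3 are the opposite-sign quadrants: a diagonal pair
  expect_true(xor(-10 >= 0, 10 >= 0) && xor(10 >= 0, -10 >= 0))
  # axis points resolve deterministically to the positive side
  expect_equal(assign_quadrant(0, 0, cfg), "Q1")
  expect_equal(assign_quadrant(0, -3, cfg), "Q3")
  expect_equal(assign_quadrant(-3, 0, cfg), "Q2")
})

test_that("every in-bounds point maps to exactly one quadrant", {
  set.seed(11)
  r <- 50 * sqrt(runif(1000))
  th <- runif(1000, 0, 2 * pi)
  q <- assign_quadrant(r * cos(th), r * sin(th), cfg)
  expect_equal(sum(table(q)), 1000)
  expect_true(all(q %in% c("Q1", "Q2", "Q3", "Q4")))
})

test_that("out-of-arena points raise an error naming the fly and frame", {
  expect_error(assign_quadrant(60, 0, cfg, fly_id = "fly7", frame = 123),
               "fly7.*frame 123")
  # jitter tolerance: 1 mm beyond the radius is accepted
  expect_equal(assign_quadrant(50.9, 0, cfg), "Q1")
})

test_that("border distance is min(|x|,|y|) with vertical-axis ties", {
  bd <- border_distance(3, 20, cfg)
  expect_equal(bd$distance, 3)
  expect_equal(bd$border, "vertical")
  bd <- border_distance(4, 4, cfg)
  expect_equal(bd$distance, 4)
  expect_equal(bd$border, "vertical")
  expect_equal(border_distance(20, 3, cfg)$border, "horizontal")
  set.seed(12)
  x <- runif(500, -35, 35); y <- runif(500, -35, 35)
  expect_equal(border_distance(x, y, cfg)$distance, pmin(abs(x), abs(y)))
})

test_that("choice-zone membership is the border band minus the center disk", {
  expect_true(in_choice_zone(4, 30, cfg))
  expect_false(in_choice_zone(4, 4, cfg))    # inside center exclusion
  expect_false(in_choice_zone(6, 30, cfg))   # outside the band
  set.seed(13)
  r <- 50 * sqrt(runif(10000))
  th <- runif(10000, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  expect_identical(in_choice_zone(x, y, cfg),
                   pmin(abs(x), abs(y)) <= 5 & sqrt(x^2 + y^2) >= 10)
})

test_that("the default protocol lights the right quadrants at the right times", {
  sch <- default_schedule()
  expect_equal(illumination_state(-10, 10, 45, sch, cfg), "lit")    # Q2 at 45 s
  expect_equal(illumination_state(-10, 10, 15, sch, cfg), "unlit")  # dark epoch
  expect_equal(illumination_state(10, 10, 100, sch, cfg), "lit")    # Q1 at 100 s
  expect_equal(illumination_state(10, 10, 45, sch, cfg), "unlit")
  expect_error(epoch_at(130, sch), "outside schedule span")
  expect_error(epoch_at(-1, sch), "outside schedule span")
})

test_that("schedules reject overlaps and non-diagonal lit sets", {
  expect_error(illumination_schedule(data.frame(
    t_start = c(0, 20), t_end = c(30, 50),
    lit = I(list(character(0), c("Q2", "Q3"))))),
    "contiguous")
  expect_error(illumination_schedule(data.frame(
    t_start = 0, t_end = 30, lit = I(list(c("Q1", "Q2"))))),
    "diagonal")
})

test_that("light intensity ramps linearly from the border to the plateau", {
  sch <- default_schedule()
  # Q2 is lit during 30-60 s; distance from the vertical border is |x|
  expect_equal(light_intensity(-10, 20, 45, sch, cfg), 34)
  expect_equal(light_intensity(-20, 25, 45, sch, cfg), 34)  # beyond the ramp
  # a point on the border belongs to Q1 by the tie rule, lit during 90-120 s
  expect_equal(light_intensity(0, 20, 100, sch, cfg), 3)
  expect_equal(light_intensity(-5, 20, 45, sch, cfg), 18.5)
  # unlit side and dark epochs are 0
  expect_equal(light_intensity(10, 20, 45, sch, cfg), 0)
  expect_equal(light_intensity(-10, 20, 15, sch, cfg), 0)
})

test_that("lit-side intensity is continuous and monotone in border distance", {
  sch <- default_schedule()
  d <- seq(0, 30, by = 0.25)
  ii <- light_intensity(d, rep(20, length(d)), 100, sch, cfg)  # Q1 lit
  expect_true(all(diff(ii[d <= 10]) >= 0))
  expect_true(all(abs(diff(ii)) <= 3.1 * 0.25 + 1e-9))  # bounded slope
  expect_equal(max(ii), 34)
  expect_equal(ii[1], 3)
})

test_that("trajectory validation enforces frames, times, bounds and reports gaps", {
  tr <- make_traj(c(0, 1, 2), c(10, 10, 10))
  expect_silent(validate_trajectories(tr, cfg))
  dup <- rbind(tr, tr[2, ])
  expect_error(validate_trajectories(dup, cfg), "duplicate frame")
  bad_t <- tr; bad_t$t_s[2] <- 1
  expect_error(validate_trajectories(bad_t, cfg), "inconsistent")
  far <- make_traj(c(0, 100), c(0, 0))
  expect_error(validate_trajectories(far, cfg), "outside the arena")
  gap <- make_traj(c(0, 1, 2), c(10, 10, 10), frames = c(0L, 1L, 5L))
  g <- attr(validate_trajectories(gap, cfg), "gaps")
  expect_equal(g$n_missing, 3L)
})
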