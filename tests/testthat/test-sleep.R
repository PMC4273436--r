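test_that("the 5-min inactivity threshold defines a sleep bout", {
  counts <- c(rep(1L, 10), rep(0L, 5), rep(1L, 10), rep(0L, 4),
              rep(1L, 1411))
  b <- detect_sleep_bouts(day_record(counts))
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 11)
  expect_equal(b$duration, 5)
  expect_equal(b$light_phase, "light")
})

test_that("bout detection equals an explicit run-length scan on random vectors", {
  set.seed(51)
  for (i in 1:200) {
    counts <- as.integer(runif(1440) < 0.6)
    got <- detect_sleep_bouts(day_record(counts))
    want <- oracle_sleep_bouts(counts)
    expect_equal(got$start, want$start)
    expect_equal(got$duration, want$duration)
  }
})

test_that("daily sleep sums bout minutes with the day/night split", {
  expect_equal(daily_sleep(day_record(rep(0L, 1440)))$sleep_min, 1440L)
  expect_equal(daily_sleep(day_record(rep(2L, 1440)))$sleep_min, 0L)
  # 100 + 30 min bouts count, the 4-min run does not
  counts <- rep(1L, 1440)
  counts[101:200] <- 0L
  counts[301:330] <- 0L
  counts[401:404] <- 0L
  ds <- daily_sleep(day_record(counts))
  expect_equal(ds$sleep_min, 130L)
  expect_equal(ds$light_sleep_min, 130L)
  expect_equal(ds$dark_sleep_min, 0L)
})

test_that("sleep plus wake minutes conserve the day on random records", {
  set.seed(52)
  for (i in 1:20) {
    rec <- day_record(as.integer(runif(2880) < 0.5), n_days = 2,
                      phases = list(baseline = 1:2))
    ds <- daily_sleep(rec)
    awake <- sum(!sleep_mask_for_test(rec))
    expect_true(all(ds$sleep_min >= 0 & ds$sleep_min <= 1440))
    expect_equal(sum(ds$sleep_min) + awake, 2880L)
    expect_equal(ds$sleep_min, ds$light_sleep_min + ds$dark_sleep_min)
  }
})

test_that("bouts spanning the day boundary are apportioned by minutes", {
  counts <- rep(1L, 2880)
  counts[1431:1450] <- 0L  # 10 min before and 10 min after midnight
  ds <- daily_sleep(day_record(counts, n_days = 2,
                               phases = list(baseline = 1:2)))
  expect_equal(ds$sleep_min, c(10L, 10L))
  expect_equal(ds$dark_sleep_min, c(10L, 0L))
  expect_equal(ds$light_sleep_min, c(0L, 10L))
})

test_that("cohort sleep profiles average per-bin sleep across flies", {
  asleep <- day_record(rep(0L, 1440))
  awake <- day_record(rep(3L, 1440))
  p <- sleep_profile(list(asleep, asleep))
  expect_equal(nrow(p), 48)
  expect_true(all(p$mean_sleep_min == 30))
  p <- sleep_profile(list(asleep, awake))
  expect_true(all(p$mean_sleep_min == 15))
})

test_that("percent sleep change compares activation days to the baseline day", {
  mk_day <- function(sleep_min) {
    c(rep(0L, sleep_min), rep(1L, 1440 - sleep_min))
  }
  phases <- list(baseline = 1:3, activation = 4:5, recovery = 6:7)
  rec <- activity_record("c1",
                         c(mk_day(600), mk_day(600), mk_day(600),
                           mk_day(300), mk_day(300), mk_day(600),
                           mk_day(600)),
                         phases = phases)
  expect_equal(percent_sleep_change(rec), -50)
  same <- activity_record("c1", rep(mk_day(400), 7), phases = phases)
  expect_equal(percent_sleep_change(same), 0)
  dead <- activity_record("c1",
                          c(mk_day(0), mk_day(0), rep(1L, 1440),
                            mk_day(300), mk_day(300), mk_day(600),
                            mk_day(600)),
                          phases = phases)
  expect_warning(out <- percent_sleep_change(dead), "undefined")
  expect_true(is.na(out))
})

test_that("waking activity is crossings per minute awake", {
  expect_equal(waking_activity(day_record(rep(2L, 1440))), 2)
  counts <- c(rep(2L, 500), rep(0L, 940))
  expect_equal(waking_activity(day_record(counts)), 1000 / 500)
  expect_warning(wa <- waking_activity(day_record(rep(0L, 1440))),
                 "no awake")
  expect_true(is.na(wa))
})

test_that("terminal inactivity of half a day flags a dead channel", {
  counts <- c(rep(2L, 720), rep(0L, 720))
  expect_true(is_dead_channel(day_record(counts)))
  expect_false(is_dead_channel(day_record(rep(2L, 1440))))
  # long mid-record sleep does not trigger the flag
  counts <- c(rep(0L, 720), rep(2L, 720))
  expect_false(is_dead_channel(day_record(counts)))
})

test_that("records reject missing bins and partial days", {
  expect_error(activity_record("c", c(rep(1L, 100), NA, rep(1L, 1339)),
                               phases = list(baseline = 1)),
               "missing")
  expect_error(activity_record("c", rep(1L, 1000),
                               phases = list(baseline = 1)),
               "whole number")
  expect_error(activity_record("c", rep(1L, 1440),
                               phases = list(baseline = 1:2)),
               "label each")
})
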