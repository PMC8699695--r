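test_that("folded profile of constant counts is flat and conserves totals", {
  a <- actogram(rep(3, 480), bin_minutes = 6)  # 2 days
  prof <- folded_profile(a, 24)
  expect_true(all(prof$mean_count == 3))
  expect_equal(nrow(prof), 240)
  # conservation over complete cycles
  set.seed(1)
  b <- actogram(rpois(480, 2), bin_minutes = 6)
  p <- folded_profile(b, 24)
  expect_equal(sum(p$mean_count) * 2, sum(b$counts))
})

test_that("a nocturnal 12:12 record folds its activity into the dark phase", {
  sched <- ld_schedule(12, 12)
  a <- gen_actogram(sched, days = 10, bin_minutes = 6, rate_dark = 5,
                    rate_light = 0.05, seed = 2)
  prof <- folded_profile(a, 24)
  dark <- !is_light(sched, prof$phase_h + a$bin_minutes / 120)
  expect_gte(sum(prof$mean_count[dark]) / sum(prof$mean_count), 0.95)
})

test_that("folding validates its period", {
  a <- actogram(rep(1, 480), bin_minutes = 6)
  expect_error(folded_profile(a, 24.05), class = "sdc_parameter_error")
  expect_error(folded_profile(actogram(rep(1, 100), 6), 24),
               class = "sdc_parameter_error")
})

test_that("total daily activity is linear and needs a full day", {
  a <- actogram(rep(0, 480), bin_minutes = 6)
  expect_equal(total_daily_activity(a), 0)
  set.seed(3)
  b <- actogram(rpois(480, 4), bin_minutes = 6)
  doubled <- actogram(2 * b$counts, bin_minutes = 6)
  expect_equal(total_daily_activity(doubled), 2 * total_daily_activity(b))
  expect_error(total_daily_activity(actogram(rep(1, 100), 6)),
               class = "sdc_insufficient_data_error")
})

test_that("daily totals equal dark-rate times dark bins in expectation", {
  # 8:8 and 12:12 schedules both give 12 dark hours per day, so with equal
  # rates the expected daily totals coincide; any group difference is a rate
  # parameter, not schedule geometry.
  for (sched in list(ld_schedule(12, 12), ld_schedule(8, 8))) {
    a <- gen_actogram(sched, days = 20, bin_minutes = 6, rate_dark = 5,
                      rate_light = 0, seed = 7)
    mid_h <- (seq_along(a$counts) - 0.5) / 10
    dark_bins_per_day <- sum(!is_light(sched, mid_h)) / 20
    expected <- 5 * dark_bins_per_day
    expect_lt(abs(total_daily_activity(a) - expected),
              3 * sqrt(expected / 20))
  }
})

test_that("pure tones are located within one grid step", {
  tt <- (seq_len(14 * 240) - 0.5) * 0.1  # 6-min bins, hours
  for (T in c(8, 16, 24)) {
    a <- actogram(10 + 5 * sin(2 * pi * tt / T), bin_minutes = 6)
    pg <- morlet_periodogram(a)
    expect_within_one_grid_step(pg$dominant_period, T)
  }
})

test_that("an 8 h on / 8 h off square wave has its 16 h fundamental dominate", {
  tt <- (seq_len(14 * 240) - 0.5) * 0.1
  sq <- actogram(ifelse(tt %% 16 < 8, 10, 0), bin_minutes = 6)
  pg <- morlet_periodogram(sq)
  expect_within_one_grid_step(pg$dominant_period, 16)
})

test_that("the dominant period is invariant to affine count rescaling", {
  a <- gen_actogram(ld_schedule(12, 12), days = 14, bin_minutes = 6,
                    rate_dark = 5, rate_light = 0.2, seed = 8)
  pg1 <- morlet_periodogram(a)
  b <- actogram(3 * a$counts + 7, bin_minutes = 6)
  pg2 <- morlet_periodogram(b)
  expect_equal(pg1$dominant_period, pg2$dominant_period)
  expect_equal(pg2$power, 9 * pg1$power, tolerance = 1e-9)
  expect_true(all(pg1$power >= 0, na.rm = TRUE))
})

test_that("noise reduction sharpens the spectral peak", {
  tt <- (seq_len(14 * 240) - 0.5) * 0.1
  base <- 10 + 5 * sin(2 * pi * tt / 24)
  ratio <- vapply(c(4, 0.5), function(sd) {
    set.seed(10)
    pg <- morlet_periodogram(actogram(pmax(base + rnorm(length(tt), 0, sd), 0),
                                      bin_minutes = 6))
    max(pg$power, na.rm = TRUE) / mean(pg$power, na.rm = TRUE)
  }, numeric(1))
  expect_gt(ratio[2], ratio[1])
})

test_that("period grids outside the valid range are rejected", {
  a <- gen_actogram(ld_schedule(12, 12), days = 3, bin_minutes = 6,
                    rate_dark = 5, rate_light = 0.2, seed = 1)
  expect_error(morlet_periodogram(a, period_min = 0.1),
               class = "sdc_parameter_error")
  expect_error(morlet_periodogram(a, period_max = 100),
               class = "sdc_parameter_error")
})
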