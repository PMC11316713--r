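test_that("degenerate config (zero amplitudes, zero noise) gives flat channels", {
  cfg <- quiet_config(seed = 1, component_amplitudes = c(0, 0, 0))
  rec <- generate_day(cfg)
  expect_equal(rec$day$mr, rep(cfg$rmr_level, 1440))
  expect_equal(rec$day$tb, rep(cfg$tb_base, 1440))
  expect_equal(rec$day$activity, rep(0, 1440))
  expect_equal(rec$day$rer, rep(cfg$rer_base, 1440))
})

test_that("generation is bit-identical under a fixed seed and leaves the RNG alone", {
  cfg <- synth_config(seed = 42)
  r1 <- generate_day(cfg)
  set.seed(999)
  before <- .Random.seed
  r2 <- generate_day(cfg)
  expect_identical(r1, r2)
  expect_identical(before, .Random.seed)
  expect_false(identical(r1$day$mr, generate_day(synth_config(seed = 43))$day$mr))
})

test_that("a generated day satisfies the record invariants", {
  for (s in c(2, 7)) {
    rec <- generate_day(synth_config(seed = s))
    d <- rec$day
    expect_length(d$mr, 1440)
    expect_true(all(d$mr >= 0))
    expect_true(all(d$activity >= 0))
    expect_true(all(d$rer >= 0.6 & d$rer <= 1.1))
    expect_true(all(rec$truth$periods_h > 0))
    expect_true(all(rec$truth$events$t_peak >= 0 &
                      rec$truth$events$t_peak <= 1439))
  }
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(component_periods = c(2, 1, 3.5)), "increasing")
  expect_error(synth_config(component_periods = c(0.2, 1, 3)), "0.3")
  expect_error(synth_config(component_periods = c(1, 3, 7)), "0.3")
  expect_error(synth_config(rer_burst_min = 1.2), "0.7")
  expect_error(synth_config(circadian_attenuation = 1.4), "attenuation")
  expect_error(synth_config(rmr_level = NaN), "finite")
  expect_error(synth_config(noise_sd = c(mr = -1, tb = 0, activity = 0,
                                         rer = 0)), "non-negative")
})

test_that("mean MR matches the closed-form pulse-area prediction", {
  cfg <- quiet_config(seed = 5)
  rec <- generate_day(cfg)
  ev <- rec$truth$events
  k <- match(ev$ur_class, c("small", "medium", "large"))
  areas <- ev$height_mr * (cfg$burst_rise[k] + cfg$burst_decay[k]) / 2
  expected <- cfg$rmr_level + sum(areas) / 1440
  # edge pulses are clipped by the day boundary, hence the tolerance
  expect_equal(mean(rec$truth$mr_clean), expected, tolerance = 0.02)
})

test_that("circadian gating attenuates light-phase burst amplitudes", {
  cfg <- quiet_config(seed = 11)
  ev <- generate_day(cfg)$truth$events
  light <- ev$t_peak >= 480 & ev$t_peak < 960
  expect_true(any(light) && any(!light))
  expect_equal(unique(ev$gate[light]), 1 - cfg$circadian_attenuation)
  expect_equal(unique(ev$gate[!light]), 1)
})

test_that("longitudinal drift: zero drift freezes periods, shared drift correlates classes", {
  recs0 <- generate_longitudinal(synth_config(seed = 9, period_drift = 0), 4)
  P0 <- t(sapply(recs0, function(r) r$truth$periods_h))
  expect_true(all(apply(P0, 2, function(v) length(unique(v)) == 1)))

  recs <- generate_longitudinal(synth_config(seed = 9), 21)
  P <- t(sapply(recs, function(r) r$truth$periods_h))
  expect_gt(cor(P[, 1], P[, 3]), 0)
  expect_gt(cor(P[, 1], P[, 2]), 0)
  expect_true(all(P >= 0.3 & P <= 6))

  expect_identical(generate_longitudinal(synth_config(seed = 4), 1)[[1]],
                   generate_day(synth_config(seed = 4), 1))
  expect_error(generate_longitudinal(synth_config(seed = 4), 0), "n_days")
})

test_that("surface-temperature traces recover injected occupancy and stay deterministic", {
  cfg <- synth_config(seed = 8)
  rec <- generate_day(cfg)
  ep <- data.frame(start_min = c(100, 400, 900),
                   end_min = c(150, 495, 950))  # 50 + 95 + 50 = 195 min
  tr <- generate_tsf_trace(cfg, rec$day, episodes = ep)
  expect_equal(outside_nest_minutes(tr)$minutes, 195)
  expect_identical(tr, generate_tsf_trace(cfg, rec$day, episodes = ep))
  expect_true(all(tr$hamster_tsf >= 5 & tr$hamster_tsf <= 45))

  # zero activity: animal trace SD sits at the noise floor, cage stays cool
  still <- rec$day
  still$activity <- rep(0, 1440)
  tr0 <- generate_tsf_trace(cfg, still,
                            episodes = data.frame(start_min = integer(0),
                                                  end_min = integer(0)))
  expect_equal(mean(activity_index(tr0)), cfg$tsf_noise, tolerance = 0.05)
  expect_lt(max(tr0$cage_tsf_1, tr0$cage_tsf_2), 16)
})
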