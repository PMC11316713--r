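test_that("a constant MR day has a flat envelope and zero ultradian share", {
  day <- physio_day(mr = rep(1.3, 1440), rer = rep(0.9, 1440))
  est <- estimate_rmr(day)
  expect_equal(est$envelope, rep(1.3, 1440))
  bud <- partition_budget(day, rmr = est)
  expect_equal(bud$ultradian_fraction, 0)
  expect_equal(bud$ultradian_kj, 0)
  expect_equal(bud$rmr_mean, 1.3)
})

test_that("the envelope tracks a noise-free synthetic baseline", {
  cfg <- quiet_config(seed = 3)
  rec <- generate_day(cfg)
  est <- estimate_rmr(rec$day, window = rec$truth$periods_h[3])
  expect_equal(est$rmr_mean, cfg$rmr_level, tolerance = 0.02)
})

test_that("the envelope follows a mid-day baseline step (locality)", {
  mr <- c(rep(0.8, 720), rep(1.4, 720))
  day <- physio_day(mr = mr, rer = rep(0.9, 1440))
  est <- estimate_rmr(day, window = 3)
  expect_equal(mean(est$envelope[1:600]), 0.8, tolerance = 1e-6)
  expect_equal(mean(est$envelope[841:1440]), 1.4, tolerance = 1e-6)
})

test_that("budget closure holds to machine precision and components are non-negative", {
  for (s in c(2, 9)) {
    rec <- generate_day(synth_config(seed = s))
    bud <- partition_budget(rec$day)
    expect_equal(bud$dee_kj, bud$rmr_kj + bud$ultradian_kj)
    expect_equal(bud$mean_mr, bud$rmr_mean + bud$ultradian_mr_mean)
    expect_equal(bud$ultradian_fraction,
                 100 * bud$ultradian_mr_mean / bud$mean_mr)
    expect_true(all(c(bud$dee_kj, bud$rmr_kj, bud$ultradian_kj) >= 0))
  }
})

test_that("raising MR by a constant shifts the envelope, not the ultradian part", {
  rec <- generate_day(synth_config(seed = 5))
  b1 <- partition_budget(rec$day, rmr = estimate_rmr(rec$day, window = 3))
  shifted <- rec$day
  shifted$mr <- shifted$mr + 0.7
  b2 <- partition_budget(shifted, rmr = estimate_rmr(shifted, window = 3))
  expect_equal(b2$rmr_mean, b1$rmr_mean + 0.7)
  expect_equal(b2$ultradian_mr_mean, b1$ultradian_mr_mean, tolerance = 1e-10)
})

test_that("12-h windows give a valid nocturnal budget", {
  rec <- generate_day(synth_config(seed = 6))
  bud <- partition_budget(rec$day, range = 961:1440)
  expect_equal(bud$window_h, 8)
  expect_equal(bud$dee_kj, bud$rmr_kj + bud$ultradian_kj)
})

test_that("cold challenge raises DEE through RMR while ultradian energy is unchanged", {
  # emulates a thermoneutral -> moderate-cold transfer: baseline up ~70%,
  # absolute ultradian drive unchanged
  warm <- quiet_config(seed = 6)
  cold <- quiet_config(seed = 6, rmr_level = 1.7,
                       component_amplitudes = c(0.2, 0.5, 1.2) / 1.7)
  bw <- partition_budget(generate_day(warm)$day)
  bc <- partition_budget(generate_day(cold)$day)
  expect_gt(bc$dee_kj, 1.3 * bw$dee_kj)
  expect_gt(bc$rmr_mean, 1.5 * bw$rmr_mean)
  expect_equal(bc$ultradian_kj, bw$ultradian_kj, tolerance = 0.05)
  expect_lt(bc$ultradian_fraction, bw$ultradian_fraction)
})

test_that("ultradian percentage arithmetic matches printed-table form", {
  expect_equal(round(ultradian_percentage(0.409, 1.822), 1), 22.4)
  expect_equal(round(ultradian_percentage(0.263, 1.092), 1), 24.1)
  expect_equal(ultradian_percentage(0, 2), 0)
})

test_that("RER dynamics recover the injected pre-burst and burst-minimum fuel mix", {
  cfg <- quiet_config(seed = 3)
  rec <- generate_day(cfg)
  lb <- detect_bursts(rec$day, period = rec$truth$periods_h[3])
  rd <- rer_burst_dynamics(rec$day, lb)
  expect_equal(rd$mean_rer_pre, cfg$rer_base, tolerance = 0.01)
  expect_equal(rd$mean_rer_min, cfg$rer_burst_min, tolerance = 0.01)
  expect_equal(rd$per_burst$mr_fold,
               lb$value_peak / lb$value_min)

  flat <- physio_day(mr = rec$day$mr, rer = rep(0.9, 1440))
  rd0 <- rer_burst_dynamics(flat, lb)
  expect_equal(rd0$mean_rer_pre - rd0$mean_rer_min, 0)
  expect_error(rer_burst_dynamics(physio_day(mr = rep(1, 1440)), lb), "RER")
})
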