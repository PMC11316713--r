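mk_peaks <- function(periods, powers = rev(seq_along(periods)),
                     significant = TRUE) {
  pk <- data.frame(period = periods, avg_power = powers,
                   prominence = powers,
                   significant = rep(significant, length.out = length(periods)))
  class(pk) <- c("period_peaks", "data.frame")
  pk
}

test_that("three peaks are assigned to classes by ascending period", {
  cp <- classify_periods(mk_peaks(c(3.91, 2.07, 0.98), c(3, 2, 1)))
  expect_equal(cp$small, 0.98)
  expect_equal(cp$medium, 2.07)
  expect_equal(cp$large, 3.91)
})

test_that("fewer peaks fall back to period bands, spreading same-band pairs", {
  one <- classify_periods(mk_peaks(0.5, 1))
  expect_equal(one$small, 0.5)
  expect_true(is.na(one$medium) && is.na(one$large))

  # two compressed peaks in the medium band become medium + large
  two <- classify_periods(mk_peaks(c(1.33, 1.91), c(2, 1)))
  expect_equal(two$medium, 1.33)
  expect_equal(two$large, 1.91)
  expect_true(is.na(two$small))

  # distinct bands map directly
  two2 <- classify_periods(mk_peaks(c(0.9, 3.0), c(2, 1)))
  expect_equal(two2$small, 0.9)
  expect_equal(two2$large, 3.0)

  empty <- classify_periods(mk_peaks(numeric(0), numeric(0)))
  expect_true(all(is.na(c(empty$small, empty$medium, empty$large))))
  none <- classify_periods(mk_peaks(c(1, 2), significant = FALSE))
  expect_true(all(is.na(c(none$small, none$medium, none$large))))
})

test_that("a single triangular pulse yields one burst with exact geometry", {
  day <- triangle_day(base = 1, peak = 3, t_min = 80, t_peak = 100)
  b <- detect_bursts(day, period = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$t_peak, 100)
  expect_equal(b$t_min, 80)
  expect_equal(b$value_min, 1)
  expect_equal(b$value_peak, 3)
  expect_equal(b$amplitude, 2)
  expect_equal(b$rise_time, 20)
})

test_that("constant series and missing inputs give no bursts / errors", {
  flat <- physio_day(mr = rep(1, 1440))
  expect_equal(nrow(detect_bursts(flat, period = 2)), 0)
  expect_error(detect_bursts(flat, period = NA_real_), "period")
  expect_error(detect_bursts(flat, period = 2, channel = "tb"), "absent")
})

test_that("burst counts on jitter-free trains match 1440/period within 1", {
  for (p_idx in c(2, 3)) {
    cfg <- solo_config(seed = 7, class = p_idx, spacing_cv = 0)
    rec <- generate_day(cfg)
    p <- rec$truth$periods_h[p_idx]
    b <- detect_bursts(rec$day, period = p)
    expect_lte(abs(nrow(b) - 1440 / (p * 60)), 1)
  }
})

test_that("noise-free amplitude recovery is exact for an isolated class", {
  cfg <- solo_config(seed = 4, class = 3, spacing_cv = 0)
  rec <- generate_day(cfg)
  b <- detect_bursts(rec$day, period = rec$truth$periods_h[3])
  inj <- rec$truth$events$height_mr[match(b$t_peak, rec$truth$events$t_peak)]
  expect_equal(b$amplitude, inj)
})

test_that("with noise, mean absolute amplitude error stays below 3 sigma", {
  sigma <- 0.05
  cfg <- solo_config(seed = 4, class = 3, spacing_cv = 0,
                     noise_sd = c(mr = sigma, tb = 0, activity = 0, rer = 0))
  rec <- generate_day(cfg)
  b <- detect_bursts(rec$day, period = rec$truth$periods_h[3], smooth = 5)
  inj <- rec$truth$events$height_mr[sapply(b$t_peak, function(tp)
    which.min(abs(rec$truth$events$t_peak - tp)))]
  expect_lt(mean(abs(b$amplitude - inj)), 3 * sigma)
})

test_that("mean burst amplitudes order small < medium < large on default data", {
  cfg <- synth_config(seed = 11)
  rec <- generate_day(cfg)
  cp <- structure(list(small = rec$truth$periods_h[1],
                       medium = rec$truth$periods_h[2],
                       large = rec$truth$periods_h[3]),
                  class = "ur_class_periods")
  bb <- extract_bursts(rec$day, cp)
  m <- tapply(bb$amplitude[!bb$superimposed], bb$ur_class[!bb$superimposed],
              mean)
  expect_lt(m[["small"]], m[["medium"]])
  expect_lt(m[["medium"]], m[["large"]])
})

test_that("percent reduction and phase split reproduce their arithmetic", {
  expect_equal(round(percent_reduction(2.31, 3.24), 1), 28.7)
  expect_equal(round(percent_reduction(1.35, 2.18), 1), 38.1)
  expect_equal(percent_reduction(5, 5), 0)

  b <- data.frame(t_min = c(10, 500), t_peak = c(30, 520),
                  value_min = c(1, 1), value_peak = c(3, 3),
                  amplitude = c(2, 2), rise_time = c(20, 20),
                  phase = c("activity", "resting"),
                  co_tb = c(1.37, 0.80), co_activity = c(10, 10),
                  superimposed = FALSE)
  ps <- phase_split(b)
  expect_equal(ps$reduction_pct[["peak"]], 0)
  expect_equal(ps$reduction_pct[["amplitude"]], 0)
  expect_equal(ps$tb_amplitude_diff_c, 0.57)

  only_act <- phase_split(b[b$phase == "activity", , drop = FALSE])
  expect_true(is.na(only_act$reduction_pct[["peak"]]))
})

test_that("threshold peak counting respects thresholds and windows", {
  cfg <- solo_config(seed = 5, class = 3, spacing_cv = 0)
  rec <- generate_day(cfg)
  p <- rec$truth$periods_h[3]
  n_all <- nrow(detect_bursts(rec$day, period = p))
  expect_equal(count_peaks_above(rec$day, p, threshold = 0), n_all)
  expect_equal(count_peaks_above(rec$day, p, threshold = 99), 0)
  first_half <- count_peaks_above(rec$day, p, threshold = 0,
                                  window = c(0, 720))
  second_half <- count_peaks_above(rec$day, p, threshold = 0,
                                   window = c(720, 1440))
  expect_equal(first_half + second_half, n_all)
})

test_that("co-occurrence fractions recover the injected coupling rates", {
  # all small bursts uncoupled from activity -> 100% lacking
  cfg0 <- solo_config(seed = 6, class = 1,
                      activity_coupling = c(0, 0, 0))
  rec0 <- generate_day(cfg0)
  b0 <- detect_bursts(rec0$day, period = rec0$truth$periods_h[1])
  b0 <- cbind(ur_class = "small", b0)
  expect_equal(burst_cooccurrence(b0)$frac_lacking_activity, 1)

  # fully coupled large bursts -> 0% lacking
  cfg1 <- solo_config(seed = 6, class = 3)
  rec1 <- generate_day(cfg1)
  b1 <- cbind(ur_class = "large",
              detect_bursts(rec1$day, period = rec1$truth$periods_h[3]))
  cc1 <- burst_cooccurrence(b1)
  expect_equal(cc1$frac_lacking_activity, 0)
  expect_equal(cc1$frac_lacking_tb, 0)

  # 40% uncoupled -> recovered within sampling error of a 24-burst day
  cfg2 <- solo_config(seed = 8, class = 1,
                      activity_coupling = c(0.6, 0.6, 0.6))
  rec2 <- generate_day(cfg2)
  b2 <- cbind(ur_class = "small",
              detect_bursts(rec2$day, period = rec2$truth$periods_h[1]))
  truth_frac <- mean(!rec2$truth$events$activity_coupled)
  got <- burst_cooccurrence(b2)$frac_lacking_activity
  expect_lt(abs(got - truth_frac), 0.15)
})
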