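test_that("a constant series has essentially zero wavelet power", {
  ws <- morlet_cwt(rep(3, 1440))
  expect_lt(max(ws$avg_power), 1e-20)
  expect_true(all(ws$power >= 0))
})

test_that("a pure sine is recovered within one period-grid step", {
  t <- 0:1439
  ws <- morlet_cwt(sin(2 * pi * t / 120))
  step <- 2^ws$dj
  expect_lt(abs(log(ws$periods[which.max(ws$avg_power)] / 2)), log(step) * 1.5)
})

test_that("FFT convolution agrees with direct time-domain convolution", {
  # independent oracle: brute-force convolution with the sampled wavelet
  set.seed(21)
  x <- rnorm(1440)
  ws <- morlet_cwt(x, rectify = FALSE, detrend = FALSE,
                   period_range = c(0.3, 1))
  xd <- x - mean(x)
  omega0 <- 6
  for (j in c(10, 40, 80)) {
    s <- ws$periods[j] * 60 / (4 * pi / (omega0 + sqrt(2 + omega0^2)))
    tt <- seq(-ceiling(6 * s), ceiling(6 * s))
    psi <- pi^(-0.25) * exp(1i * omega0 * tt / s) * exp(-(tt / s)^2 / 2) / sqrt(s)
    mid <- 400:700  # interior: wavelet support stays inside the series
    direct <- vapply(mid, function(i)
      abs(sum(xd[i + tt] * Conj(psi)))^2, numeric(1))
    expect_equal(ws$power[mid, j], direct, tolerance = 1e-6)
  }
})

test_that("two well-separated sines give two periodogram peaks at their periods", {
  t <- 0:1439
  x <- sin(2 * pi * t / 60) + sin(2 * pi * t / 234)
  pk <- find_period_peaks(morlet_cwt(x))
  expect_equal(nrow(pk), 2)
  got <- sort(pk$period)
  expect_equal(got[1], 1, tolerance = 0.03)
  expect_equal(got[2], 234 / 60, tolerance = 0.03)
})

test_that("power is shift-invariant and scales quadratically with amplitude", {
  set.seed(4)
  x <- sin(2 * pi * (0:1439) / 90) + rnorm(1440, 0, 0.1)
  a1 <- morlet_cwt(x)$avg_power
  expect_equal(morlet_cwt(x + 7)$avg_power, a1, tolerance = 1e-10)
  expect_equal(morlet_cwt(3 * x)$avg_power, 9 * a1, tolerance = 1e-10)
})

test_that("spectrum grid and cone of influence honour their invariants", {
  ws <- morlet_cwt(rnorm(1440))
  expect_true(all(diff(ws$periods) > 0))
  expect_true(all(ws$periods >= 0.3 - 1e-9 & ws$periods <= 6 + 1e-9))
  expect_equal(ws$avg_power, colMeans(ws$power))
  expect_equal(ws$coi[1], 0)
  mid <- which.max(ws$coi)
  expect_gt(ws$coi[mid], 6)        # centre of the day is unaffected to 6 h
  expect_error(morlet_cwt(c(rep(NA_real_, 200), rnorm(1240))), "missing")
})

test_that("shuffle thresholds are seeded, monotone in alpha, and detect a sine", {
  set.seed(10)
  x <- sin(2 * pi * (0:1439) / 120) + rnorm(1440, 0, 0.5)
  t1 <- shuffle_significance(x, n_shuffles = 30, alpha = 0.05, seed = 7)
  t2 <- shuffle_significance(x, n_shuffles = 30, alpha = 0.05, seed = 7)
  expect_identical(t1$threshold, t2$threshold)
  t3 <- shuffle_significance(x, n_shuffles = 30, alpha = 0.2, seed = 7)
  expect_true(all(t3$threshold <= t1$threshold))

  thr <- shuffle_significance(x, n_shuffles = 99, alpha = 0.01, seed = 1,
                              pointwise = FALSE)
  ws <- add_significance(morlet_cwt(x), thr)
  pk <- find_period_peaks(ws)
  hit <- which.min(abs(pk$period - 2))
  expect_true(pk$significant[hit])
  expect_lt(abs(pk$period[hit] - 2), 0.1)

  expect_error(shuffle_significance(x, n_shuffles = 0), "n_shuffles")
  expect_error(shuffle_significance(x, alpha = 1.2), "alpha")
})

test_that("peak finding handles degenerate periodograms", {
  expect_equal(nrow(find_period_peaks(bare_spectrum(seq(0, 1, length.out = 50)))), 0)
  expect_equal(nrow(find_period_peaks(bare_spectrum(rep(0, 50)))), 0)
  one <- find_period_peaks(morlet_cwt(sin(2 * pi * (0:1439) / 150)))
  expect_equal(nrow(one), 1)
})
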