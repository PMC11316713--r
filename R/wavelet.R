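#' Morlet continuous wavelet transform of a per-minute series
#'
#' Computes the continuous wavelet transform of a regularly sampled series
#' with the analytic Morlet wavelet (a complex sine tapered by a Gaussian,
#' centre-frequency parameter `omega0 = 6`), on a log-spaced scale grid
#' restricted to the ultradian period band 0.3--6 h. The transform is
#' evaluated by FFT convolution with zero padding to the next power of two;
#' the cone of influence (periods whose estimate at a given time is affected
#' by the series edges) is recorded per sample. Scales are converted to
#' Fourier periods with the standard Morlet factor
#' \eqn{4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})}.
#'
#' Power is the squared modulus of the transform, by default rectified by
#' scale (divided by the scale) so that oscillations of equal amplitude at
#' different periods reach comparable periodogram peaks; set
#' `rectify = FALSE` for the raw squared modulus. The time-averaged power per
#' period (`avg_power`) averages over the full window, including samples
#' under the cone of influence.
#'
#' @param x Numeric series on a regular grid (`NA`s tolerated up to
#'   `max_na_frac` and linearly interpolated), or a [physio_day()] combined
#'   with `channel`.
#' @param channel Channel name when `x` is a `physio_day`.
#' @param dt Sampling interval in minutes.
#' @param period_range Analysed period band in hours.
#' @param omega0 Morlet centre-frequency parameter.
#' @param dj Scale resolution in octave fractions (grid step factor
#'   `2^dj`).
#' @param rectify Divide power by scale (bias-corrected periodogram)?
#' @param detrend Remove a linear trend before transforming?
#' @param max_na_frac Maximum tolerated fraction of missing samples.
#' @return An object of class `wavelet_spectrum`: list with `periods` (hours,
#'   increasing), `times` (minutes), `power` (time x period matrix, >= 0),
#'   `avg_power` (per period), `coi` (cone-of-influence boundary per time,
#'   hours), and the transform parameters.
#' @export
#' @examples
#' x <- sin(2 * pi * (0:1439) / 120)  # 2-h oscillation
#' ws <- morlet_cwt(x)
#' ws$periods[which.max(ws$avg_power)]
morlet_cwt <- function(x, channel = "mr", dt = 1, period_range = c(0.3, 6),
                       omega0 = 6, dj = 1 / 50, rectify = TRUE,
                       detrend = TRUE, max_na_frac = 0.05) {
  if (inherits(x, "physio_day")) {
    if (is.null(x[[channel]])) stop("channel '", channel, "' absent")
    x <- as.numeric(x[[channel]])
  }
  plan <- cwt_plan(length(x), dt, period_range, omega0, dj)
  cwt_apply(x, plan, rectify = rectify, detrend = detrend,
            max_na_frac = max_na_frac, channel = channel)
}

# Precomputed transform machinery (scale grid, frequency-domain daughter
# wavelets, COI) for a given series length; reused across surrogates.
cwt_plan <- function(n, dt = 1, period_range = c(0.3, 6), omega0 = 6,
                     dj = 1 / 50) {
  if (n < 4) stop("series too short")
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  pmin_m <- period_range[1] * 60
  pmax_m <- period_range[2] * 60
  s0 <- pmin_m / ff
  J <- ceiling(log2(pmax_m / pmin_m) / dj)
  scales <- s0 * 2^(dj * (0:J))
  scales <- scales[scales * ff <= pmax_m * (1 + 1e-9)]

  npad <- 2^ceiling(log2(n))
  k <- 0:(npad - 1)
  omega <- 2 * pi * k / (npad * dt)
  omega[k > npad / 2] <- -omega[k > npad / 2]
  pos <- omega > 0
  norm <- sqrt(2 * pi * scales / dt) * pi^(-0.25)
  arg <- outer(omega, scales)                 # omega * s
  daug <- matrix(0, npad, length(scales))
  daug[pos, ] <- exp(-(arg[pos, , drop = FALSE] - omega0)^2 / 2)
  daug <- sweep(daug, 2, norm, `*`)

  dist <- pmin(k[seq_len(n)], n - 1 - k[seq_len(n)]) * dt  # minutes to edge
  list(n = n, npad = npad, dt = dt, scales = scales, daug = daug,
       periods = scales * ff / 60, coi = ff * dist / sqrt(2) / 60,
       omega0 = omega0, dj = dj)
}

cwt_apply <- function(x, plan, rectify = TRUE, detrend = TRUE,
                      max_na_frac = 0.05, channel = NA_character_) {
  n <- plan$n
  stopifnot(length(x) == n)
  if (anyNA(x)) {
    if (mean(is.na(x)) > max_na_frac)
      stop(sprintf("more than %.0f%% of samples missing", 100 * max_na_frac))
    idx <- seq_len(n)
    x <- approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
  }
  xd <- if (detrend) {
    stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  } else x - mean(x)

  xf <- stats::fft(c(xd, numeric(plan$npad - n)))
  W <- stats::mvfft(plan$daug * as.vector(xf), inverse = TRUE) / plan$npad
  W <- W[seq_len(n), , drop = FALSE]
  power <- Mod(W)^2
  if (rectify) power <- sweep(power, 2, plan$scales, `/`)

  structure(list(periods = plan$periods,
                 times = (seq_len(n) - 1) * plan$dt,
                 power = power,
                 avg_power = colMeans(power),
                 coi = plan$coi,
                 omega0 = plan$omega0, dj = plan$dj, dt = plan$dt,
                 rectify = rectify, n = n,
                 channel = channel),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d samples x %d periods (%.2f-%.2f h)\n",
              x$n, length(x$periods), min(x$periods), max(x$periods)))
  cat(sprintf("  peak of time-averaged power at %.2f h\n",
              x$periods[which.max(x$avg_power)]))
  if (!is.null(x$sig_threshold))
    cat(sprintf("  surrogate threshold attached (alpha = %g, n = %d)\n",
                x$sig_alpha, x$sig_n))
  invisible(x)
}

#' Shuffle-surrogate significance thresholds for wavelet power
#'
#' Builds an empirical null for the time-averaged wavelet power by randomly
#' permuting the original samples (destroying all temporal structure while
#' keeping the marginal distribution of the data), recomputing the
#' periodogram for each surrogate, and taking as per-period threshold the
#' `m`-th largest surrogate value with `m = floor(alpha * (n_shuffles + 1))`.
#' A real periodogram value exceeding the threshold is significant at level
#' `m / (n_shuffles + 1)`; choosing `n_shuffles` so that
#' `alpha * (n_shuffles + 1)` is an integer (e.g. 59 or 99 for alpha = 0.05)
#' makes the test exact at `alpha`. A pooled threshold for the time-resolved
#' power map is computed the same way from the pooled instantaneous surrogate
#' power.
#'
#' @param x Numeric series (or `physio_day` plus `channel`) -- the *original*
#'   data; the observed spectrum is recomputed internally with identical
#'   transform parameters so that real and surrogate statistics are exactly
#'   comparable.
#' @param n_shuffles Number of random permutations (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param seed Integer seed for the permutation stream.
#' @param ... Passed on to [morlet_cwt()].
#' @inheritParams morlet_cwt
#' @return An object of class `shuffle_threshold`: `periods`, `threshold`
#'   (per-period avg-power threshold), `threshold_map` (per-period pointwise
#'   threshold for the time-resolved mask), `alpha`, `n_shuffles`, `seed`.
#' @export
shuffle_significance <- function(x, n_shuffles = 150, alpha = 0.05,
                                 seed = 1L, channel = "mr",
                                 pointwise = TRUE, ...) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (inherits(x, "physio_day")) {
    if (is.null(x[[channel]])) stop("channel '", channel, "' absent")
    x <- as.numeric(x[[channel]])
  }
  dots <- list(...)
  plan <- cwt_plan(length(x),
                   dt = dots$dt %||% 1,
                   period_range = dots$period_range %||% c(0.3, 6),
                   omega0 = dots$omega0 %||% 6,
                   dj = dots$dj %||% (1 / 50))
  rectify <- dots$rectify %||% TRUE
  detrend <- dots$detrend %||% TRUE
  nper <- length(plan$periods)
  surr_avg <- matrix(NA_real_, n_shuffles, nper)
  m <- max(1L, min(n_shuffles, floor(alpha * (n_shuffles + 1))))
  pool <- if (pointwise) matrix(NA_real_, n_shuffles, nper) else NULL
  with_seed(seed, {
    for (b in seq_len(n_shuffles)) {
      ws <- cwt_apply(sample(x), plan, rectify = rectify, detrend = detrend)
      surr_avg[b, ] <- ws$avg_power
      if (pointwise)
        # per-surrogate pointwise (1 - alpha) quantile per period; the map
        # threshold averages these across surrogates (smooth, memory-stable)
        pool[b, ] <- matrixStats_colQuantile(ws$power, 1 - alpha)
    }
  })
  q_hi <- apply(surr_avg, 2, function(col) sort(col, decreasing = TRUE)[m])
  structure(list(periods = plan$periods,
                 threshold = q_hi,
                 threshold_map = if (pointwise) colMeans(pool) else NULL,
                 alpha = alpha,
                 level = m / (n_shuffles + 1),
                 n_shuffles = n_shuffles,
                 seed = seed),
            class = "shuffle_threshold")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-wise empirical quantile (type 7) without per-column dispatch
# overhead.
matrixStats_colQuantile <- function(m, p) {
  n <- nrow(m)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  frac <- h - lo
  apply(m, 2, function(col) {
    s <- sort.int(col, partial = c(lo, min(lo + 1, n)))
    s[lo] + frac * (s[min(lo + 1, n)] - s[lo])
  })
}

#' @export
print.shuffle_threshold <- function(x, ...) {
  cat(sprintf(paste0("<shuffle_threshold> %d permutations, alpha = %g ",
                     "(realized level %.4f)\n"),
              x$n_shuffles, x$alpha, x$level))
  invisible(x)
}

#' Attach surrogate thresholds to a wavelet spectrum
#'
#' Stores the per-period avg-power threshold and the time-resolved
#' significance mask (`power > threshold_map`) on the spectrum object, for
#' use by [find_period_peaks()] and plotting.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param threshold A `shuffle_threshold` computed from the same series and
#'   transform parameters.
#' @return The spectrum with `sig_threshold`, `sig_mask`, `sig_alpha`,
#'   `sig_n` filled in.
#' @export
add_significance <- function(spectrum, threshold) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"),
            inherits(threshold, "shuffle_threshold"))
  if (length(threshold$periods) != length(spectrum$periods))
    stop("threshold computed on a different period grid")
  spectrum$sig_threshold <- threshold$threshold
  if (!is.null(threshold$threshold_map))
    spectrum$sig_mask <- sweep(spectrum$power, 2, threshold$threshold_map, `>`)
  spectrum$sig_alpha <- threshold$alpha
  spectrum$sig_n <- threshold$n_shuffles
  spectrum
}

#' Peaks of the time-averaged wavelet periodogram
#'
#' Finds local maxima of the time-averaged power, keeps those whose
#' topographic prominence is at least `min_prominence` times the maximum
#' average power and which are at least `min_separation` grid steps from a
#' stronger retained peak, and orders them by descending power (ties broken
#' towards shorter periods). If the spectrum carries surrogate thresholds
#' (see [add_significance()]), each peak is flagged significant when its
#' average power exceeds the per-period threshold.
#'
#' @param spectrum A `wavelet_spectrum`.
#' @param min_prominence Minimum peak prominence as a fraction of the maximum
#'   average power.
#' @param min_separation Minimum separation between retained peaks, in period
#'   grid steps.
#' @return A data.frame of class `period_peaks` with columns `period` (h),
#'   `avg_power`, `prominence` and `significant` (logical, `NA` when no
#'   threshold is attached); zero rows when the periodogram has no interior
#'   local maximum.
#' @export
find_period_peaks <- function(spectrum, min_prominence = 0.005,
                              min_separation = 12) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  avg <- spectrum$avg_power
  if (!length(avg)) stop("empty spectrum")
  empty <- data.frame(period = numeric(0), avg_power = numeric(0),
                      prominence = numeric(0), significant = logical(0))
  class(empty) <- c("period_peaks", "data.frame")
  if (max(avg) <= 0) return(empty)
  cand <- pracma::findpeaks(avg, nups = 1, ndowns = 1)
  if (is.null(cand)) return(empty)
  idx <- cand[, 2]
  prom <- vapply(idx, function(i) peak_prominence(avg, i), numeric(1))
  keep <- prom >= min_prominence * max(avg)
  idx <- idx[keep]
  prom <- prom[keep]
  if (!length(idx)) return(empty)
  # order: descending power, then shorter period
  o <- order(-avg[idx], spectrum$periods[idx])
  idx <- idx[o]
  prom <- prom[o]
  sel <- logical(length(idx))
  taken <- integer(0)
  for (i in seq_along(idx)) {
    if (!length(taken) || all(abs(idx[i] - taken) >= min_separation)) {
      sel[i] <- TRUE
      taken <- c(taken, idx[i])
    }
  }
  idx <- idx[sel]
  prom <- prom[sel]
  sig <- if (!is.null(spectrum$sig_threshold))
    avg[idx] > spectrum$sig_threshold[idx] else rep(NA, length(idx))
  out <- data.frame(period = spectrum$periods[idx],
                    avg_power = avg[idx],
                    prominence = prom,
                    significant = sig)
  class(out) <- c("period_peaks", "data.frame")
  out
}

# Topographic prominence of a local maximum: height above the higher of the
# two lowest saddles separating it from higher terrain (or the series edge).
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i - 1
  while (j >= 1 && y[j] <= y[i]) {
    left_min <- min(left_min, y[j])
    j <- j - 1
  }
  if (j < 1) left_min <- min(y[1:i])
  right_min <- y[i]
  j <- i + 1
  while (j <= n && y[j] <= y[i]) {
    right_min <- min(right_min, y[j])
    j <- j + 1
  }
  if (j > n) right_min <- min(y[i:n])
  y[i] - max(left_min, right_min)
}
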