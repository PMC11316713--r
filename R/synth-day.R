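#' @importFrom stats rnorm runif approx quantile cor cor.test sd lm coef
NULL

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so generators do not disturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for (config seed, stream id, day index); kept well
# below 2^31.
sub_seed <- function(seed, stream, day_index = 0L) {
  (abs(seed) * 97L + stream * 7919L + day_index * 104729L) %% 2147483587L
}

MINUTES_PER_DAY <- 1440L

#' Realized ultradian periods for one simulated day
#'
#' The three class periods follow a shared multiplicative (log-scale) random
#' walk across days plus independent per-class jitter, so classes co-vary from
#' day to day without being exact harmonics. Day 1 anchors the walk at the
#' configured base periods. The whole path up to `day_index` is recomputed
#' deterministically from the config seed, so day `d` of a longitudinal run
#' equals a standalone call for day `d`.
#'
#' @param config A [synth_config()].
#' @param day_index Day number (1-based).
#' @return Numeric vector of three periods in hours (small, medium, large).
#' @export
realized_periods <- function(config, day_index = 1L) {
  stopifnot(day_index >= 1)
  base <- log(config$component_periods)
  drift <- config$period_drift
  jit_sd <- drift / 2
  with_seed(sub_seed(config$seed, 1L), {
    shared <- c(0, rnorm(max(0L, day_index - 1L), 0, drift))
    s <- cumsum(shared)[day_index]
    jit <- if (day_index > 1L || drift > 0) {
      m <- matrix(rnorm(3L * day_index, 0, jit_sd), nrow = 3L)
      m[, day_index]
    } else rep(0, 3L)
    p <- exp(base + s + jit)
    pmin(pmax(p, 0.31), 5.9)
  })
}

# Half-cosine asymmetric pulse: unit height, rise r and decay d minutes,
# peaking at integer minute `peak`. Adds `h * pulse` into `y` (length n,
# minute grid 0..n-1) and returns y.
add_pulse <- function(y, peak, h, r, d) {
  n <- length(y)
  t0 <- max(0L, ceiling(peak - r))
  t1 <- min(n - 1L, floor(peak + d))
  if (t1 < t0) return(y)
  t <- t0:t1
  v <- ifelse(t <= peak,
              (1 - cos(pi * (t - (peak - r)) / r)) / 2,
              (1 + cos(pi * (t - peak) / d)) / 2)
  idx <- t + 1L
  y[idx] <- y[idx] + h * v
  y
}

pulse_values <- function(t, peak, r, d) {
  v <- numeric(length(t))
  up <- t >= (peak - r) & t <= peak
  dn <- t > peak & t <= (peak + d)
  v[up] <- (1 - cos(pi * (t[up] - (peak - r)) / r)) / 2
  v[dn] <- (1 + cos(pi * (t[dn] - peak) / d)) / 2
  v
}

# Event peak times (integer minutes) for one class, generated from one period
# before the day to one pulse width after it so edge pulses have realistic
# tails. Events sit on the phase grid of an underlying oscillator (random
# phase per day) with independent Gaussian timing jitter of SD cv * period
# around each grid point: spacings vary visibly but timing errors do not
# accumulate across the day, keeping the per-day spectral line narrow.
class_events <- function(period_min, cv, width) {
  u <- runif(1, 0, period_min)
  grid <- seq(u - period_min, MINUTES_PER_DAY + width, by = period_min)
  if (cv > 0) grid <- grid + rnorm(length(grid), 0, cv * period_min)
  sort(round(grid))
}

#' Generate one synthetic 24-h physiological record with ground truth
#'
#' Simulates a 1-min-grid day (n = 1440) of metabolic rate, RER, core body
#' temperature and locomotor activity as a resting baseline plus three
#' superimposed quasi-periodic ultradian burst trains, with circadian gating
#' of burst amplitudes during the light phase, probabilistic coupling of
#' bursts into the T_b and activity channels (first-order thermal lag for
#' T_b), RER depression during large bursts, and additive Gaussian noise.
#'
#' @param config A [synth_config()].
#' @param day_index Day number; selects the day's realized periods along the
#'   configured period random walk and the day's private RNG stream.
#' @param subject_id Identifier stored in the record.
#' @return A list with elements `day` (a `physio_day`) and `truth` (a
#'   `ground_truth` list holding the realized class periods in hours, the
#'   per-event table with injected per-channel heights and coupling flags,
#'   the injected RMR trace, the noise-free channel traces, and the injected
#'   ultradian fractions of mean MR and of daily energy).
#' @export
#' @examples
#' rec <- generate_day(synth_config(seed = 42))
#' range(rec$day$mr)
#' rec$truth$periods_h
generate_day <- function(config, day_index = 1L, subject_id = "synthetic-1") {
  validate_synth_config(config)
  periods_h <- realized_periods(config, day_index)
  n <- MINUTES_PER_DAY
  tmin <- 0:(n - 1L)
  lp_min <- config$light_phase * 60

  with_seed(sub_seed(config$seed, 2L, as.integer(day_index)), {
    mr_clean <- rep(config$rmr_level, n)
    act_clean <- numeric(n)
    tb_drive <- numeric(n)
    dip <- numeric(n)  # unit-height large-class envelope for the RER dip

    ev <- list()
    for (k in 1:3) {
      if (config$component_amplitudes[k] == 0) next  # class absent
      P <- periods_h[k] * 60
      r <- config$burst_rise[k]
      d <- config$burst_decay[k]
      peaks <- class_events(P, config$spacing_cv, r + d)
      if (!length(peaks)) next
      gate <- ifelse(peaks >= lp_min[1] & peaks < lp_min[2],
                     1 - config$circadian_attenuation, 1)
      h_mr <- config$component_amplitudes[k] * config$rmr_level * gate
      tb_cpl <- runif(length(peaks)) < config$tb_coupling[k]
      act_cpl <- runif(length(peaks)) < config$activity_coupling[k]
      for (i in seq_along(peaks)) {
        mr_clean <- add_pulse(mr_clean, peaks[i], h_mr[i], r, d)
        if (act_cpl[i])
          act_clean <- add_pulse(act_clean, peaks[i],
                                 config$activity_gain[k] * gate[i], r, d)
        if (tb_cpl[i])
          tb_drive <- add_pulse(tb_drive, peaks[i],
                                config$tb_gain[k] * gate[i], r, d)
        if (k == 3L) {
          v <- pulse_values(tmin, peaks[i], r, d)
          dip <- pmax(dip, v)
        }
      }
      inside <- peaks >= 0 & peaks <= n - 1L
      if (any(inside))
        ev[[k]] <- data.frame(ur_class = c("small", "medium", "large")[k],
                              t_peak = peaks[inside],
                              t_start = peaks[inside] - r,
                              height_mr = h_mr[inside],
                              height_tb = ifelse(tb_cpl[inside],
                                                 config$tb_gain[k] *
                                                   gate[inside], 0),
                              height_activity = ifelse(act_cpl[inside],
                                                       config$activity_gain[k] *
                                                         gate[inside], 0),
                              tb_coupled = tb_cpl[inside],
                              activity_coupled = act_cpl[inside],
                              gate = gate[inside])
    }
    events <- do.call(rbind, ev)
    if (!is.null(events)) events <- events[order(events$t_peak), ]

    # first-order low-pass for the T_b response (thermal inertia)
    tb_clean <- rep(config$tb_base, n)
    if (config$tb_lag > 0) {
      a <- 1 - exp(-1 / config$tb_lag)
      f <- 0
      for (i in seq_len(n)) {
        f <- f + a * (tb_drive[i] - f)
        tb_clean[i] <- config$tb_base + f
      }
    } else tb_clean <- config$tb_base + tb_drive

    rer_clean <- config$rer_base -
      (config$rer_base - config$rer_burst_min) * pmin(dip, 1)

    mr <- pmax(mr_clean + rnorm(n, 0, config$noise_sd[["mr"]]), 0)
    tb <- tb_clean + rnorm(n, 0, config$noise_sd[["tb"]])
    activity <- pmax(round(act_clean +
                             rnorm(n, 0, config$noise_sd[["activity"]])), 0)
    rer <- pmin(pmax(rer_clean + rnorm(n, 0, config$noise_sd[["rer"]]),
                     0.7), 1.0)

    day <- physio_day(mr = mr, rer = rer, tb = tb, activity = activity,
                      subject_id = subject_id,
                      day_index = as.integer(day_index),
                      light_phase = config$light_phase, ta = config$ta)

    rmr_trace <- rep(config$rmr_level, n)
    uf_mr <- mean(mr_clean - rmr_trace) / mean(mr_clean)
    hp_tot <- heat_production(mr_clean * 60, rer_clean)
    hp_rmr <- heat_production(rmr_trace * 60, rer_clean)
    uf_energy <- 1 - sum(hp_rmr) / sum(hp_tot)

    truth <- structure(list(periods_h = periods_h,
                            events = events,
                            rmr_trace = rmr_trace,
                            mr_clean = mr_clean,
                            tb_clean = tb_clean,
                            activity_clean = act_clean,
                            rer_clean = rer_clean,
                            ultradian_fraction_mr = uf_mr,
                            ultradian_fraction_energy = uf_energy),
                       class = "ground_truth")
    list(day = day, truth = truth)
  })
}

#' Generate a longitudinal sequence of synthetic days
#'
#' Day-to-day class periods follow the configured shared multiplicative random
#' walk plus independent per-class jitter (see [realized_periods()]); each
#' day's record is otherwise generated as by [generate_day()], and the two
#' agree exactly for matching `day_index`.
#'
#' @param config A [synth_config()].
#' @param n_days Number of consecutive days (>= 1).
#' @param subject_id Identifier shared by all days.
#' @return A list of `n_days` elements, each a `list(day, truth)`.
#' @export
generate_longitudinal <- function(config, n_days, subject_id = "synthetic-1") {
  if (n_days < 1) stop("n_days must be >= 1")
  lapply(seq_len(n_days), function(d)
    generate_day(config, day_index = d, subject_id = subject_id))
}

#' Construct a 24-h multichannel physiological record
#'
#' A `physio_day` holds one subject-day of per-minute channels on a regular
#' 1-min grid (n = 1440): metabolic rate (mL O2 min^-1), RER, core body
#' temperature (degrees C) and locomotor activity (counts min^-1). Channels
#' may individually be `NULL` (absent) but never partially gapped beyond
#' isolated `NA`s.
#'
#' @param mr,rer,tb,activity Channel vectors of length 1440 or `NULL`.
#' @param subject_id,day_index Identifiers.
#' @param light_phase Light-phase clock interval in decimal hours.
#' @param ta Ambient temperature, degrees C.
#' @param date Calendar date of the record start.
#' @return An object of class `physio_day`.
#' @export
physio_day <- function(mr = NULL, rer = NULL, tb = NULL, activity = NULL,
                       subject_id = "subject-1", day_index = 1L,
                       light_phase = c(8, 16), ta = NA_real_,
                       date = as.Date("2023-11-01") + day_index - 1L) {
  for (ch in list(mr = mr, rer = rer, tb = tb, activity = activity)) {
    if (!is.null(ch) && length(ch) != MINUTES_PER_DAY)
      stop("each present channel must have exactly 1440 samples (1-min grid)")
  }
  if (!is.null(mr) && any(mr < 0, na.rm = TRUE))
    stop("mr must be non-negative")
  if (!is.null(activity) && any(activity < 0, na.rm = TRUE))
    stop("activity must be non-negative")
  if (!is.null(rer) && any(rer < 0.6 | rer > 1.1, na.rm = TRUE))
    stop("rer must lie within [0.6, 1.1]")
  structure(list(minute = 0:(MINUTES_PER_DAY - 1L),
                 mr = mr, rer = rer, tb = tb, activity = activity,
                 subject_id = subject_id, day_index = as.integer(day_index),
                 light_phase = light_phase, ta = ta, date = date),
            class = "physio_day")
}

#' @export
print.physio_day <- function(x, ...) {
  chans <- c("mr", "rer", "tb", "activity")
  have <- chans[!vapply(x[chans], is.null, logical(1))]
  cat(sprintf("<physio_day> %s day %d (%s)\n", x$subject_id, x$day_index,
              format(x$date)))
  cat(sprintf("  channels: %s (1440 samples, 1-min grid)\n",
              paste(have, collapse = ", ")))
  if (!is.null(x$mr))
    cat(sprintf("  MR mean %.3f mL O2 min^-1, range %.3f-%.3f\n",
                mean(x$mr, na.rm = TRUE), min(x$mr, na.rm = TRUE),
                max(x$mr, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.physio_day <- function(x, ...) {
  ts <- format(as.POSIXct(x$date, tz = "UTC") + x$minute * 60,
               "%Y-%m-%dT%H:%M:%S")
  df <- data.frame(timestamp = ts, stringsAsFactors = FALSE)
  df$mr_mlo2_min <- if (is.null(x$mr)) NA_real_ else x$mr
  df$rer <- if (is.null(x$rer)) NA_real_ else x$rer
  df$tb_c <- if (is.null(x$tb)) NA_real_ else x$tb
  df$activity_counts <- if (is.null(x$activity)) NA_real_ else x$activity
  df
}

# Minute-of-day membership in the half-open light-phase interval.
in_light_phase <- function(minute, light_phase) {
  minute >= light_phase[1] * 60 & minute < light_phase[2] * 60
}
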