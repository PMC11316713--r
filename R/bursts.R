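#' Assign periodogram peaks to the three ultradian classes
#'
#' Retains up to three (significant) periodogram peaks, strongest first, and
#' assigns them to the small/medium/large ultradian classes. With three peaks
#' the assignment is purely by ascending period. With fewer, peaks fall into
#' the period bands small \[0.3, 1.25) h, medium \[1.25, 2.4) h, large
#' \[2.4, 6\] h; when two peaks land in the same band they are spread over
#' adjacent classes preserving period order (two compressed peaks at, say,
#' 1.33 and 1.91 h become medium and large).
#'
#' @param peaks A `period_peaks` data.frame from [find_period_peaks()]. Rows
#'   with `significant == FALSE` are dropped; `NA` significance (no surrogate
#'   threshold attached) is treated as eligible.
#' @param bands Inner band edges (hours) separating small/medium and
#'   medium/large for the fallback assignment.
#' @param max_peaks Maximum number of peaks retained (strongest first).
#' @return An object of class `ur_class_periods`: list with numeric `small`,
#'   `medium`, `large` (hours, `NA` when unassigned) and the peak table used.
#' @export
#' @examples
#' pk <- data.frame(period = c(3.91, 2.07, 0.98),
#'                  avg_power = c(3, 2, 1), prominence = c(3, 2, 1),
#'                  significant = TRUE)
#' class(pk) <- c("period_peaks", "data.frame")
#' classify_periods(pk)
classify_periods <- function(peaks, bands = c(1.25, 2.4), max_peaks = 3) {
  out <- list(small = NA_real_, medium = NA_real_, large = NA_real_,
              peaks = peaks)
  class(out) <- "ur_class_periods"
  if (is.null(peaks) || !nrow(peaks)) return(out)
  keep <- is.na(peaks$significant) | peaks$significant
  pk <- peaks[keep, , drop = FALSE]
  if (!nrow(pk)) return(out)
  pk <- pk[order(-pk$avg_power, pk$period), , drop = FALSE]
  pk <- utils::head(pk, max_peaks)
  p <- sort(pk$period)
  if (length(p) == 3) {
    out$small <- p[1]; out$medium <- p[2]; out$large <- p[3]
  } else if (length(p) == 2) {
    band <- findInterval(p, c(0.3, bands[1], bands[2]))
    if (band[1] == band[2]) {
      # same band: spread over adjacent classes, keeping period order
      lo <- if (band[1] == 3) 2L else band[1]
      band <- c(lo, lo + 1L)
    }
    slots <- c("small", "medium", "large")
    out[[slots[band[1]]]] <- p[1]
    out[[slots[band[2]]]] <- p[2]
  } else if (length(p) == 1) {
    band <- findInterval(p, c(0.3, bands[1], bands[2]))
    out[[c("small", "medium", "large")[band]]] <- p
  }
  out
}

#' @export
print.ur_class_periods <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.2f h", v)
  cat(sprintf("<ur_class_periods> small %s | medium %s | large %s\n",
              fmt(x$small), fmt(x$medium), fmt(x$large)))
  invisible(x)
}

#' Extract individual ultradian bursts with a period-adapted search window
#'
#' Scans the channel with a sliding search window whose width equals the
#' class period (times `search_frac`): a sample is a candidate peak when it
#' is the maximum of its window. Candidates closer than `min_gap_frac` times
#' the period to a stronger peak are discarded, and peaks whose search window
#' is truncated by the day edge are dropped. For each retained peak the
#' preceding minimum is located within one period before the peak; the burst
#' amplitude is peak minus minimum and the rise time their separation in
#' minutes. Each burst is labelled with its circadian phase (`"resting"`
#' when the peak falls in the light phase, `"activity"` otherwise) and, when
#' the other channels are present, with the co-amplitudes of T_b (evaluated
#' with the thermal lag) and activity over the same rise window.
#'
#' When a resting-metabolic-rate envelope and the day's large-class amplitude
#' are supplied, bursts whose minimum sits more than a quarter of the
#' large-class amplitude above the envelope are flagged `superimposed` (they
#' ride on top of a large burst rather than starting near baseline) so that
#' baseline statistics can exclude them.
#'
#' @param day A [physio_day()].
#' @param period Class period in hours.
#' @param channel Channel searched for bursts (default `"mr"`).
#' @param search_frac Search-window width as a fraction of the period.
#' @param min_gap_frac Minimum distance between retained peaks, as a fraction
#'   of the period.
#' @param baseline Optional per-minute RMR envelope (length 1440).
#' @param large_amplitude Optional day-level large-class amplitude used by
#'   the `superimposed` flag.
#' @param superimposed_frac Tolerance above the envelope, as a fraction of
#'   `large_amplitude`.
#' @param tb_lag Thermal lag (minutes) applied when reading the T_b
#'   co-amplitude.
#' @param smooth Odd running-average window (minutes) applied to the searched
#'   channel before extraction; 1 (default) searches the raw series. A window
#'   of ~5 min is recommended for noisy records: window extrema of a noisy
#'   series are biased outwards (peaks high, minima low), inflating
#'   amplitudes.
#' @return A data.frame of class `burst_table`, one row per burst: `t_min`,
#'   `t_peak` (minute-of-day, 0-based), `value_min`, `value_peak`,
#'   `amplitude`, `rise_time`, `phase`, `co_tb`, `co_activity`,
#'   `superimposed`.
#' @export
detect_bursts <- function(day, period, channel = "mr", search_frac = 1,
                          min_gap_frac = 0.5, baseline = NULL,
                          large_amplitude = NULL, superimposed_frac = 0.25,
                          tb_lag = 10, smooth = 1) {
  if (is.na(period) || is.null(period)) stop("period missing")
  y <- day[[channel]]
  if (is.null(y)) stop("channel '", channel, "' absent")
  # light smoothing tempers the extreme-value bias of window maxima/minima
  # on noisy records; the default leaves the series untouched
  if (smooth > 1) y <- running_average(y, smooth)
  n <- length(y)
  p_min <- round(period * 60)
  w <- max(3L, round(p_min * search_frac))
  half <- floor(w / 2)

  empty <- burst_table_frame()
  # candidate peaks: window maxima with some variation inside the window
  cand <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    win <- y[lo:hi]
    if (y[i] >= max(win) && y[i] > min(win)) cand <- c(cand, i)
  }
  if (!length(cand)) return(empty)
  # de-duplicate: keep the larger peak within min_gap_frac * period
  gap <- max(1L, round(min_gap_frac * p_min))
  cand <- cand[order(-y[cand], cand)]
  keep <- integer(0)
  for (i in cand) if (!length(keep) || all(abs(i - keep) >= gap))
    keep <- c(keep, i)
  keep <- sort(keep)
  # drop peaks too close to the start of the day to evaluate the preceding
  # minimum (their search window is truncated by the day edge)
  keep <- keep[keep > half]
  if (!length(keep)) return(empty)

  rows <- lapply(keep, function(i) {
    lo <- max(1L, i - p_min)
    seg <- y[lo:(i - 1L)]
    j <- max(which(seg == min(seg)))          # minimum closest to the peak
    t_min_idx <- lo + j - 1L
    v_min <- y[t_min_idx]
    co_tb <- NA_real_
    if (!is.null(day$tb)) {
      a <- min(n, t_min_idx + tb_lag)
      b <- min(n, i + tb_lag)
      co_tb <- day$tb[b] - day$tb[a]
    }
    co_act <- NA_real_
    if (!is.null(day$activity)) {
      seg_a <- day$activity[t_min_idx:i]
      co_act <- max(seg_a) - seg_a[1]
    }
    sup <- FALSE
    if (!is.null(baseline) && !is.null(large_amplitude) &&
        is.finite(large_amplitude))
      sup <- v_min > baseline[t_min_idx] + superimposed_frac * large_amplitude
    data.frame(t_min = t_min_idx - 1L, t_peak = i - 1L,
               value_min = v_min, value_peak = y[i],
               amplitude = y[i] - v_min, rise_time = i - t_min_idx,
               phase = if (in_light_phase(i - 1L, day$light_phase))
                 "resting" else "activity",
               co_tb = co_tb, co_activity = co_act,
               superimposed = sup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("burst_table", "data.frame")
  out
}

burst_table_frame <- function() {
  out <- data.frame(t_min = integer(0), t_peak = integer(0),
                    value_min = numeric(0), value_peak = numeric(0),
                    amplitude = numeric(0), rise_time = integer(0),
                    phase = character(0), co_tb = numeric(0),
                    co_activity = numeric(0), superimposed = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Extract bursts for all assigned ultradian classes of a day
#'
#' Runs [detect_bursts()] once per assigned class period and binds the
#' results with a `ur_class` column. The day's large-class amplitude (median
#' amplitude of large bursts) and the RMR envelope feed the
#' baseline-proximity flag for the small and medium classes.
#'
#' @param day A [physio_day()].
#' @param class_periods An `ur_class_periods` (or list with `small`,
#'   `medium`, `large` in hours).
#' @param channel Channel to search.
#' @param ... Passed to [detect_bursts()].
#' @return A `burst_table` with a leading `ur_class` column.
#' @export
extract_bursts <- function(day, class_periods, channel = "mr", ...) {
  env <- if (identical(channel, "mr"))
    estimate_rmr(day, window = if (!is.na(class_periods$large))
      class_periods$large else 3)$envelope else NULL
  large <- if (!is.na(class_periods$large))
    detect_bursts(day, class_periods$large, channel = channel, ...) else NULL
  large_amp <- if (!is.null(large) && nrow(large))
    stats::median(large$amplitude) else NA_real_
  pieces <- list()
  for (cls in c("small", "medium", "large")) {
    p <- class_periods[[cls]]
    if (is.na(p)) next
    b <- if (cls == "large" && !is.null(large)) large
    else detect_bursts(day, p, channel = channel, baseline = env,
                       large_amplitude = large_amp, ...)
    if (cls != "large" && !is.null(large) && nrow(large) && nrow(b)) {
      # a small/medium window placed on a large burst finds the large peak
      # itself; flag such coincident peaks as superimposed duplicates
      dup <- vapply(b$t_peak, function(tp)
        any(abs(tp - large$t_peak) <= 0.5 * p * 60), logical(1))
      b$superimposed <- b$superimposed | dup
    }
    if (nrow(b)) {
      b <- cbind(ur_class = cls, b, stringsAsFactors = FALSE)
      pieces[[cls]] <- b
    }
  }
  if (!length(pieces)) {
    out <- cbind(ur_class = character(0), burst_table_frame())
  } else out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Percent reduction of a resting-phase mean relative to the activity phase
#'
#' The attenuation statistic used for circadian gating of ultradian bursts:
#' `100 * (1 - resting / activity)`.
#'
#' @param resting,activity Phase means (same units).
#' @return Percent reduction (negative when the resting mean is larger).
#' @export
#' @examples
#' percent_reduction(2.31, 3.24)  # ~28.7
percent_reduction <- function(resting, activity) {
  100 * (1 - resting / activity)
}

#' Compare ultradian bursts between circadian resting and activity phase
#'
#' Splits a burst table by circadian phase of the peak and summarises, per
#' phase, the mean peak value, mean driving-channel amplitude and mean T_b /
#' activity co-amplitudes, together with the percent reduction during the
#' resting phase (and the absolute degrees-C difference for the T_b
#' co-amplitude). A phase with zero bursts yields `NA` comparisons.
#'
#' @param bursts A `burst_table` (bursts labelled with `phase`).
#' @return A list of class `phase_split`: `resting` and `activity`
#'   (per-phase means and counts), `reduction_pct` (named vector for
#'   `peak`, `amplitude`, `activity`), `tb_amplitude_diff_c`.
#' @export
phase_split <- function(bursts) {
  one <- function(ph) {
    b <- bursts[bursts$phase == ph, , drop = FALSE]
    list(n = nrow(b),
         mean_peak = if (nrow(b)) mean(b$value_peak) else NA_real_,
         mean_amplitude = if (nrow(b)) mean(b$amplitude) else NA_real_,
         mean_co_tb = if (nrow(b)) mean(b$co_tb) else NA_real_,
         mean_co_activity = if (nrow(b)) mean(b$co_activity) else NA_real_)
  }
  r <- one("resting")
  a <- one("activity")
  red <- c(peak = percent_reduction(r$mean_peak, a$mean_peak),
           amplitude = percent_reduction(r$mean_amplitude, a$mean_amplitude),
           activity = percent_reduction(r$mean_co_activity,
                                        a$mean_co_activity))
  structure(list(resting = r, activity = a,
                 reduction_pct = red,
                 tb_amplitude_diff_c = a$mean_co_tb - r$mean_co_tb),
            class = "phase_split")
}

#' @export
print.phase_split <- function(x, ...) {
  cat("<phase_split>\n")
  cat(sprintf("  resting : n = %d, mean peak %.3f, mean amplitude %.3f\n",
              x$resting$n, x$resting$mean_peak, x$resting$mean_amplitude))
  cat(sprintf("  activity: n = %d, mean peak %.3f, mean amplitude %.3f\n",
              x$activity$n, x$activity$mean_peak, x$activity$mean_amplitude))
  cat(sprintf("  reduction during resting: peak %.1f%%, amplitude %.1f%%\n",
              x$reduction_pct["peak"], x$reduction_pct["amplitude"]))
  invisible(x)
}

#' Count burst peaks exceeding a threshold within a clock window
#'
#' Detects bursts at the given period and counts those whose peak value
#' exceeds the threshold and whose peak time falls inside the window. Used
#' for summaries of the form "number of peaks per 12 h above 2 mL O2
#' min^-1".
#'
#' @param day A [physio_day()].
#' @param period Search-window period, hours.
#' @param threshold Peak-value threshold in channel units (0 counts every
#'   burst).
#' @param window Minute-of-day interval `c(from, to)`, half-open; default the
#'   whole day.
#' @param channel Channel searched.
#' @param ... Passed to [detect_bursts()].
#' @return Integer count.
#' @export
count_peaks_above <- function(day, period, threshold = 2,
                              window = c(0, 1440), channel = "mr", ...) {
  b <- detect_bursts(day, period, channel = channel, ...)
  if (!nrow(b)) return(0L)
  sum(b$value_peak > threshold & b$t_peak >= window[1] & b$t_peak < window[2])
}

#' Fractions of metabolic bursts lacking a T_b or activity response
#'
#' For each ultradian class, the fraction of MR bursts whose T_b
#' (respectively activity) co-amplitude over the rise window is not positive
#' -- i.e. the metabolic burst was not accompanied by a body-temperature or
#' locomotor response.
#'
#' @param bursts A `burst_table` with a `ur_class` column and co-amplitudes
#'   populated (see [extract_bursts()]).
#' @return A data.frame with one row per class: `ur_class`, `n`,
#'   `frac_lacking_tb`, `frac_lacking_activity`.
#' @export
burst_cooccurrence <- function(bursts) {
  cls <- intersect(c("small", "medium", "large"), unique(bursts$ur_class))
  rows <- lapply(cls, function(cl) {
    b <- bursts[bursts$ur_class == cl, , drop = FALSE]
    data.frame(ur_class = cl, n = nrow(b),
               frac_lacking_tb = mean(b$co_tb <= 0),
               frac_lacking_activity = mean(b$co_activity <= 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
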