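#' Full per-day ultradian analysis
#'
#' Composes the pipeline stages for one 24-h record: torpor screening
#' (days whose body temperature dips below `torpor_tb_cutoff` are excluded
#' from ultradian analysis), Morlet wavelet spectrum with shuffle-surrogate
#' significance per channel, periodogram peak extraction and class
#' assignment, per-class burst extraction on the MR channel, RMR-envelope
#' energy partition, and the circadian phase split of large bursts.
#'
#' @param day A [physio_day()].
#' @param channels Channels to analyse (present ones are used).
#' @param n_shuffles Surrogates for periodogram significance; `0` skips the
#'   surrogate test (all periodogram peaks are then eligible for class
#'   assignment, useful for quick looks).
#' @param alpha_peaks Significance level for periodogram peaks.
#' @param alpha_map Significance level for the time-resolved mask.
#' @param torpor_tb_cutoff Body-temperature cutoff (degrees C) below which
#'   the day is flagged as containing torpor and excluded.
#' @param seed Seed for the surrogate permutation stream.
#' @param ... Passed to [morlet_cwt()].
#' @return A list of class `ur_day_report`. When the day is excluded:
#'   `excluded = TRUE` and `reason`. Otherwise: `spectra` and `periods` (per
#'   channel), `bursts` (MR burst table with classes), `budget`
#'   (an `energy_budget`), `phase` (a `phase_split` of large MR bursts),
#'   `rer_dynamics`, and `params`.
#' @export
run_day <- function(day, channels = c("mr", "tb", "activity"),
                    n_shuffles = 150, alpha_peaks = 0.01, alpha_map = 0.05,
                    torpor_tb_cutoff = 32, seed = 1L, ...) {
  stopifnot(inherits(day, "physio_day"))
  if (!is.null(day$tb) && any(day$tb < torpor_tb_cutoff, na.rm = TRUE)) {
    return(structure(list(excluded = TRUE,
                          reason = sprintf(
                            "torpor: T_b fell below %.1f degrees C",
                            torpor_tb_cutoff),
                          subject_id = day$subject_id,
                          day_index = day$day_index),
                     class = "ur_day_report"))
  }
  channels <- channels[!vapply(day[channels], is.null, logical(1))]
  if (!length(channels)) stop("no analyzable channels present")

  spectra <- list()
  periods <- list()
  for (ch in channels) {
    ws <- morlet_cwt(day, channel = ch, ...)
    if (n_shuffles > 0) {
      thr <- shuffle_significance(day, channel = ch,
                                  n_shuffles = n_shuffles,
                                  alpha = alpha_peaks, seed = seed,
                                  pointwise = FALSE, ...)
      ws <- add_significance(ws, thr)
    }
    spectra[[ch]] <- ws
    periods[[ch]] <- classify_periods(find_period_peaks(ws))
  }

  bursts <- NULL
  budget <- NULL
  phase <- NULL
  rerdyn <- NULL
  if ("mr" %in% channels) {
    cp <- periods$mr
    bursts <- extract_bursts(day, cp)
    env <- estimate_rmr(day, window = if (!is.na(cp$large)) cp$large else 3)
    if (!is.null(day$rer)) budget <- partition_budget(day, rmr = env)
    lb <- bursts[bursts$ur_class == "large", , drop = FALSE]
    if (nrow(lb)) {
      phase <- phase_split(lb)
      if (!is.null(day$rer)) rerdyn <- rer_burst_dynamics(day, lb)
    }
  }
  structure(list(excluded = FALSE,
                 subject_id = day$subject_id, day_index = day$day_index,
                 spectra = spectra, periods = periods, bursts = bursts,
                 budget = budget, phase = phase, rer_dynamics = rerdyn,
                 params = list(n_shuffles = n_shuffles,
                               alpha_peaks = alpha_peaks,
                               alpha_map = alpha_map,
                               torpor_tb_cutoff = torpor_tb_cutoff,
                               seed = seed)),
            class = "ur_day_report")
}

#' @export
print.ur_day_report <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat(sprintf("<ur_day_report> %s day %d EXCLUDED (%s)\n",
                x$subject_id, x$day_index, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<ur_day_report> %s day %d\n", x$subject_id, x$day_index))
  for (ch in names(x$periods)) {
    p <- x$periods[[ch]]
    fmt <- function(v) if (is.na(v)) "--" else sprintf("%.2f", v)
    cat(sprintf("  %-8s periods [h]: small %s, medium %s, large %s\n",
                ch, fmt(p$small), fmt(p$medium), fmt(p$large)))
  }
  if (!is.null(x$budget))
    cat(sprintf("  DEE %.2f kJ, ultradian fraction %.1f%% of mean MR\n",
                x$budget$dee_kj, x$budget$ultradian_fraction))
  invisible(x)
}

#' Longitudinal multi-day ultradian analysis
#'
#' Runs [run_day()] on each day, assembles the day-by-day period time-course
#' per channel and class, computes the pairwise period synchrony
#' (class-vs-class within each variable) and its summary, and a Table-style
#' per-class summary of burst properties (mean +/- SEM).
#'
#' @param days A list of [physio_day()] objects (or of `list(day, truth)`
#'   pairs as returned by [generate_longitudinal()]), at least 5 analyzable
#'   days.
#' @param ... Passed to [run_day()].
#' @return A list of class `ur_study_report`: `day_reports`, `timecourse`
#'   (a [period_timecourse()]), `synchrony` (a `synchrony_table`),
#'   `synchrony_summary`, `class_summary` (per-class burst statistics),
#'   `excluded` (indices of excluded days).
#' @export
run_longitudinal <- function(days, ...) {
  days <- lapply(days, function(d) if (inherits(d, "physio_day")) d else d$day)
  reports <- lapply(days, run_day, ...)
  ok <- !vapply(reports, function(r) isTRUE(r$excluded), logical(1))
  if (sum(ok) < 5)
    stop("fewer than 5 analyzable days after exclusions")

  rows <- list()
  for (i in which(ok)) {
    rep_i <- reports[[i]]
    for (ch in names(rep_i$periods)) {
      p <- rep_i$periods[[ch]]
      for (cls in c("small", "medium", "large"))
        rows[[length(rows) + 1L]] <-
          data.frame(day = rep_i$day_index, variable = ch, class = cls,
                     period = p[[cls]], stringsAsFactors = FALSE)
    }
  }
  tc <- period_timecourse(do.call(rbind, rows))
  sync <- pairwise_correlations(tc, pairs = "within_variable")

  all_bursts <- do.call(rbind, lapply(reports[ok], function(r) r$bursts))
  class_summary <- NULL
  if (!is.null(all_bursts) && nrow(all_bursts)) {
    sem <- function(v) sd(v) / sqrt(length(v))
    class_summary <- do.call(rbind, lapply(
      intersect(c("small", "medium", "large"), unique(all_bursts$ur_class)),
      function(cl) {
        b <- all_bursts[all_bursts$ur_class == cl &
                          !all_bursts$superimposed, , drop = FALSE]
        data.frame(ur_class = cl, n_bursts = nrow(b),
                   bursts_per_day = nrow(b) / sum(ok),
                   mean_peak = mean(b$value_peak), sem_peak = sem(b$value_peak),
                   mean_amplitude = mean(b$amplitude),
                   sem_amplitude = sem(b$amplitude),
                   mean_rise_min = mean(b$rise_time),
                   stringsAsFactors = FALSE)
      }))
  }
  structure(list(day_reports = reports,
                 timecourse = tc,
                 synchrony = sync,
                 synchrony_summary = synchrony_summary(sync),
                 class_summary = class_summary,
                 excluded = which(!ok)),
            class = "ur_study_report")
}

#' @export
print.ur_study_report <- function(x, ...) {
  cat(sprintf("<ur_study_report> %d days (%d excluded)\n",
              length(x$day_reports), length(x$excluded)))
  print(x$synchrony_summary)
  if (!is.null(x$class_summary)) {
    cat("  per-class burst summary:\n")
    print(x$class_summary, row.names = FALSE)
  }
  invisible(x)
}
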