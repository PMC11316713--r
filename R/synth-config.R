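#' Configuration for the synthetic physiological-day generator
#'
#' Builds and validates the parameter set from which [generate_day()] and
#' [generate_longitudinal()] simulate 24-h multichannel records (metabolic
#' rate, RER, core body temperature, locomotor activity) carrying three
#' superimposed ultradian oscillations of increasing period and amplitude.
#'
#' The defaults describe a short-photoperiod Djungarian-hamster-like animal at
#' moderate cold: a resting metabolic rate around 1 mL O2 min^-1 with ultradian
#' burst classes at roughly 1, 2 and 3.5 h whose peak heights are about +20%,
#' +50% and +120% of RMR. Large-class bursts co-drive locomotor activity and
#' (with thermal lag) body temperature and depress RER from `rer_base` towards
#' `rer_burst_min`; small-class bursts are mostly of metabolic origin and only
#' probabilistically couple to the other channels. Burst amplitudes are
#' attenuated by `circadian_attenuation` during the light (resting) phase.
#'
#' @param rmr_level Resting metabolic rate baseline, mL O2 min^-1.
#' @param component_periods Periods of the small/medium/large ultradian
#'   classes, hours; strictly increasing, all within 0.3--6 h.
#' @param component_amplitudes Burst peak heights as fractions of `rmr_level`
#'   for the three classes.
#' @param burst_rise,burst_decay Rise and decay durations of the burst pulse
#'   per class, minutes. The pulse is an asymmetric half-cosine (fast rise,
#'   slower decay).
#' @param spacing_cv Coefficient of variation of the lognormal inter-burst
#'   spacing jitter around the class period (0 gives strictly periodic trains).
#' @param circadian_attenuation Fractional amplitude reduction applied to
#'   bursts peaking during the light phase.
#' @param light_phase Clock interval of the light (resting) phase in decimal
#'   hours, half-open `[from, to)`.
#' @param tb_base Core body temperature baseline, degrees C.
#' @param tb_gain Body-temperature pulse height per class, degrees C.
#' @param tb_lag First-order thermal lag (time constant) of the T_b response,
#'   minutes.
#' @param tb_coupling,activity_coupling Per-class probabilities that a burst
#'   couples into the T_b (resp. activity) channel.
#' @param activity_gain Activity pulse height per class, counts min^-1.
#' @param rer_base,rer_burst_min Respiratory exchange ratio at rest and at the
#'   peak of a large burst (large bursts shift fuel use towards lipids).
#' @param noise_sd Named numeric vector of additive Gaussian noise SDs for
#'   channels `mr`, `tb`, `activity`, `rer`.
#' @param period_drift Day-to-day multiplicative random-walk SD (log scale) of
#'   the shared period drift; the independent per-class jitter SD is tied to
#'   it (`period_drift / 2`) so that zero drift gives identical periods on
#'   every day.
#' @param ta Ambient temperature, degrees C (metadata; also the cage-floor
#'   surface temperature baseline for [generate_tsf_trace()]).
#' @param tsf_noise Surface-temperature noise floor of the animal trace at
#'   rest, degrees C per 1-s sample.
#' @param tsf_act_gain Additional within-minute surface-temperature SD per
#'   activity count, degrees C.
#' @param seed Integer seed; the same seed and config give bit-identical
#'   output.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_day()], [generate_longitudinal()], [generate_tsf_trace()]
#' @export
#' @examples
#' cfg <- synth_config(seed = 7)
#' cfg$component_periods
synth_config <- function(rmr_level = 1.0,
                         component_periods = c(1.0, 2.0, 3.5),
                         component_amplitudes = c(0.2, 0.5, 1.2),
                         burst_rise = c(13, 25, 40),
                         burst_decay = c(22, 45, 90),
                         spacing_cv = 0.05,
                         circadian_attenuation = 0.4,
                         light_phase = c(8, 16),
                         tb_base = 36.0,
                         tb_gain = c(0.05, 0.30, 1.20),
                         tb_lag = 10,
                         tb_coupling = c(0.32, 1, 1),
                         activity_coupling = c(0.56, 0.79, 1),
                         activity_gain = c(1.2, 0.3, 15),
                         rer_base = 0.96,
                         rer_burst_min = 0.84,
                         noise_sd = c(mr = 0.05, tb = 0.05,
                                      activity = 0.5, rer = 0.01),
                         period_drift = 0.06,
                         ta = 15,
                         tsf_noise = 0.15,
                         tsf_act_gain = 0.08,
                         seed = 1L) {
  cfg <- list(rmr_level = rmr_level,
              component_periods = component_periods,
              component_amplitudes = component_amplitudes,
              burst_rise = burst_rise,
              burst_decay = burst_decay,
              spacing_cv = spacing_cv,
              circadian_attenuation = circadian_attenuation,
              light_phase = light_phase,
              tb_base = tb_base,
              tb_gain = tb_gain,
              tb_lag = tb_lag,
              tb_coupling = tb_coupling,
              activity_coupling = activity_coupling,
              activity_gain = activity_gain,
              rer_base = rer_base,
              rer_burst_min = rer_burst_min,
              noise_sd = noise_sd,
              period_drift = period_drift,
              ta = ta,
              tsf_noise = tsf_noise,
              tsf_act_gain = tsf_act_gain,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num)))
    stop("synth_config: all parameters must be finite")
  p <- cfg$component_periods
  if (length(p) != 3L || any(diff(p) <= 0))
    stop("component_periods must be three strictly increasing values")
  if (any(p < 0.3) || any(p > 6))
    stop("component_periods must lie within [0.3, 6] h")
  if (length(cfg$component_amplitudes) != 3L ||
      any(cfg$component_amplitudes < 0))
    stop("component_amplitudes must be three non-negative fractions")
  if (cfg$circadian_attenuation < 0 || cfg$circadian_attenuation > 1)
    stop("circadian_attenuation must lie within [0, 1]")
  if (any(cfg$noise_sd < 0))
    stop("noise_sd values must be non-negative")
  for (nm in c("mr", "tb", "activity", "rer"))
    if (!nm %in% names(cfg$noise_sd))
      stop("noise_sd must name channels mr, tb, activity, rer")
  for (r in c(cfg$rer_base, cfg$rer_burst_min))
    if (r < 0.7 || r > 1.0)
      stop("RER parameters must lie within [0.7, 1.0]")
  if (cfg$rer_burst_min > cfg$rer_base)
    stop("rer_burst_min must not exceed rer_base")
  if (any(cfg$burst_rise <= 0) || any(cfg$burst_decay <= 0))
    stop("burst rise/decay durations must be positive")
  if (cfg$spacing_cv < 0 || cfg$period_drift < 0)
    stop("spacing_cv and period_drift must be non-negative")
  lp <- cfg$light_phase
  if (length(lp) != 2L || lp[1] < 0 || lp[2] > 24 || lp[1] >= lp[2])
    stop("light_phase must be an increasing clock interval within [0, 24]")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  RMR baseline      : %.3f mL O2 min^-1\n", x$rmr_level))
  cat(sprintf("  class periods     : %s h\n",
              paste(format(x$component_periods), collapse = " / ")))
  cat(sprintf("  class amplitudes  : %s x RMR\n",
              paste(format(x$component_amplitudes), collapse = " / ")))
  cat(sprintf("  light phase       : %02d:00-%02d:00 (attenuation %.0f%%)\n",
              x$light_phase[1], x$light_phase[2],
              100 * x$circadian_attenuation))
  cat(sprintf("  period drift sd   : %.3f (log scale, per day)\n",
              x$period_drift))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}
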