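# Shared fixture builders: all synthetic, generated at test time.

quiet_config <- function(seed = 1, ...) {
  synth_config(seed = seed,
               noise_sd = c(mr = 0, tb = 0, activity = 0, rer = 0), ...)
}

# A day carrying a single burst class (others zeroed), noise-free unless
# overridden.
solo_config <- function(seed, class = 3, amplitude = NULL,
                        noise_sd = c(mr = 0, tb = 0, activity = 0, rer = 0),
                        ...) {
  amps <- c(0, 0, 0)
  amps[class] <- if (is.null(amplitude)) c(0.2, 0.5, 1.2)[class] else amplitude
  synth_config(seed = seed, component_amplitudes = amps, noise_sd = noise_sd,
               ...)
}

# Minimal hand-built day: flat MR with one triangular burst.
triangle_day <- function(base = 1, peak = 3, t_min = 80, t_peak = 100,
                         t_end = 130) {
  mr <- rep(base, 1440)
  up <- t_min:t_peak
  mr[up + 1] <- base + (peak - base) * (up - t_min) / (t_peak - t_min)
  dn <- t_peak:t_end
  mr[dn + 1] <- base + (peak - base) * (t_end - dn) / (t_end - t_peak)
  physio_day(mr = mr, rer = rep(0.9, 1440))
}

bare_spectrum <- function(avg_power, periods = NULL) {
  if (is.null(periods))
    periods <- exp(seq(log(0.3), log(6), length.out = length(avg_power)))
  structure(list(periods = periods, avg_power = avg_power,
                 power = matrix(avg_power, nrow = 1, byrow = TRUE),
                 n = 1440),
            class = "wavelet_spectrum")
}
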