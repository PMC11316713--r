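#' Resting-metabolic-rate envelope of a day
#'
#' Tracks the resting metabolic rate through the minima of the ultradian
#' bursts: the MR series is reduced to non-overlapping 6-min averages, a
#' centred rolling minimum with a window equal to the day's large-class
#' period picks out the local burst minima, and the envelope is linearly
#' interpolated between those anchor minima (so a slow change of baseline is
#' tracked rather than flattened to a global minimum). The daily RMR is the
#' mean of the envelope (`method = "envelope"`, default) or the mean of the
#' anchor minima themselves (`method = "minima"`).
#'
#' @param day A [physio_day()] with an MR channel (or a plain numeric
#'   per-minute MR series).
#' @param window Rolling-minimum window in hours; use the day's large-class
#'   ultradian period (fallback 3 h) so that medium bursts are not swallowed.
#' @param bin Averaging bin in minutes (6-min averages).
#' @param method How the daily RMR is averaged.
#' @return A list of class `rmr_estimate`: `envelope` (per-minute, length of
#'   the input), `rmr_mean` (mL O2 min^-1), `anchors` (data.frame of anchor
#'   minute and value), `window_h`, `method`.
#' @export
estimate_rmr <- function(day, window = 3, bin = 6,
                         method = c("envelope", "minima")) {
  method <- match.arg(method)
  y <- if (inherits(day, "physio_day")) day$mr else as.numeric(day)
  if (is.null(y)) stop("MR channel missing")
  n <- length(y)
  nb <- floor(n / bin)
  bm <- colMeans(matrix(y[seq_len(nb * bin)], nrow = bin))
  wb <- min(nb, max(1L, round(window * 60 / bin)))
  halfb <- floor(wb / 2)
  # centred rolling minimum; the window keeps its full width near the day
  # edges by shifting inward (a shrinking window would inflate edge anchors)
  rmin <- vapply(seq_len(nb), function(i) {
    lo <- max(1L, min(i - halfb, nb - wb + 1L))
    min(bm[lo:min(nb, lo + wb - 1L)])
  }, numeric(1))
  anchor <- which(bm <= rmin + 1e-12)
  # linear interpolation between anchor minima; where it would overshoot an
  # intermediate bin mean, that bin joins the anchor set (the envelope must
  # never exceed the smoothed series it is an envelope of)
  repeat {
    env_b <- approx((anchor - 0.5) * bin, bm[anchor],
                    xout = (seq_len(nb) - 0.5) * bin, rule = 2)$y
    viol <- which(bm < env_b - 1e-12)
    if (!length(viol)) break
    anchor <- sort(union(anchor, viol))
  }
  centres <- (anchor - 0.5) * bin            # bin centres in minutes
  env_bin <- approx(centres, bm[anchor],
                    xout = (seq_len(n) - 0.5), rule = 2)$y
  rmr_mean <- if (method == "envelope") mean(env_bin) else mean(bm[anchor])
  structure(list(envelope = env_bin,
                 rmr_mean = rmr_mean,
                 anchors = data.frame(minute = centres, value = bm[anchor]),
                 window_h = window, method = method),
            class = "rmr_estimate")
}

#' @export
print.rmr_estimate <- function(x, ...) {
  cat(sprintf("<rmr_estimate> daily RMR %.3f mL O2 min^-1 (%s, %d anchors)\n",
              x$rmr_mean, x$method, nrow(x$anchors)))
  invisible(x)
}

#' Partition the daily energy budget into resting and ultradian metabolism
#'
#' The ultradian MR series is the excess of MR over the RMR envelope (floored
#' at zero, since noise can dip below the envelope); the resting series is
#' the remainder, so mean MR decomposes exactly into resting plus ultradian
#' components. Each component is converted to energy with the day's RER via
#' [heat_production()], which is linear in VO2, so the daily energy
#' expenditure satisfies `dee_kj == rmr_kj + ultradian_kj` to machine
#' precision.
#'
#' @param day A [physio_day()] with MR and RER channels.
#' @param rmr An `rmr_estimate` (computed with [estimate_rmr()] defaults when
#'   omitted).
#' @param range Optional minute indices (1-based) restricting the window,
#'   e.g. `721:1440` for a nocturnal 12-h budget.
#' @return An object of class `energy_budget`: `dee_kj`, `rmr_kj`,
#'   `ultradian_kj` (kJ per window), `mean_mr`, `rmr_mean`,
#'   `ultradian_mr_mean` (mL O2 min^-1), `ultradian_fraction` (% of mean
#'   MR), `mean_hp_mw`, `window_h`.
#' @export
partition_budget <- function(day, rmr = NULL, range = NULL) {
  if (is.null(day$mr)) stop("MR channel missing")
  if (is.null(day$rer)) stop("RER channel missing")
  if (is.null(rmr)) rmr <- estimate_rmr(day)
  env <- rmr$envelope
  mr <- day$mr
  rer <- fill_rer(day$rer)
  if (!is.null(range)) {
    mr <- mr[range]; env <- env[range]; rer <- rer[range]
  }
  ultra <- pmax(mr - env, 0)
  rest <- mr - ultra
  secs <- length(mr) * 60
  hp_tot <- heat_production(mr * 60, rer)
  hp_rest <- heat_production(rest * 60, rer)
  hp_ultra <- hp_tot - hp_rest
  structure(list(dee_kj = mean(hp_tot) * secs / 1e6,
                 rmr_kj = mean(hp_rest) * secs / 1e6,
                 ultradian_kj = mean(hp_ultra) * secs / 1e6,
                 mean_mr = mean(mr),
                 rmr_mean = mean(rest),
                 ultradian_mr_mean = mean(ultra),
                 ultradian_fraction = ultradian_percentage(mean(ultra),
                                                           mean(mr)),
                 mean_hp_mw = mean(hp_tot),
                 window_h = length(mr) / 60),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> %g-h window\n", x$window_h))
  cat(sprintf("  DEE %.2f kJ = RMR %.2f + ultradian %.2f kJ\n",
              x$dee_kj, x$rmr_kj, x$ultradian_kj))
  cat(sprintf("  mean MR %.3f = RMR %.3f + ultradian %.3f mL O2 min^-1\n",
              x$mean_mr, x$rmr_mean, x$ultradian_mr_mean))
  cat(sprintf("  ultradian fraction %.1f%% of mean MR\n",
              x$ultradian_fraction))
  invisible(x)
}

#' Ultradian share of mean metabolic rate
#'
#' @param ultradian_mr,mean_mr Component and total mean MR (same units).
#' @return Percentage `100 * ultradian_mr / mean_mr`.
#' @export
#' @examples
#' ultradian_percentage(0.409, 1.822)  # ~22.4
ultradian_percentage <- function(ultradian_mr, mean_mr) {
  100 * ultradian_mr / mean_mr
}

#' RER dynamics across large ultradian bursts
#'
#' For each burst, compares the RER at the burst minimum (pre-burst fuel mix)
#' with the minimum RER reached during the burst span, alongside the MR
#' fold-change from minimum to peak. A drop of RER during the metabolic burst
#' indicates rerouting from carbohydrate towards lipid oxidation.
#'
#' @param day A [physio_day()] with MR and RER channels.
#' @param bursts A `burst_table` (typically the large class).
#' @param span_frac Burst span searched for the RER minimum, as a multiple of
#'   the rise time beyond the peak.
#' @return A list of class `rer_dynamics`: per-burst data.frame (`rer_pre`,
#'   `rer_min`, `mr_fold`) and the across-burst means `mean_rer_pre`,
#'   `mean_rer_min`, `mean_fold`.
#' @export
rer_burst_dynamics <- function(day, bursts, span_frac = 1) {
  if (is.null(day$rer)) stop("RER channel missing")
  if (is.null(day$mr)) stop("MR channel missing")
  n <- length(day$rer)
  if (!nrow(bursts))
    return(structure(list(per_burst = data.frame(), mean_rer_pre = NA_real_,
                          mean_rer_min = NA_real_, mean_fold = NA_real_),
                     class = "rer_dynamics"))
  per <- do.call(rbind, lapply(seq_len(nrow(bursts)), function(k) {
    i0 <- bursts$t_min[k] + 1L
    i1 <- bursts$t_peak[k] + 1L
    i2 <- min(n, i1 + round(span_frac * (i1 - i0)))
    data.frame(rer_pre = day$rer[i0],
               rer_min = min(day$rer[i0:i2]),
               mr_fold = bursts$value_peak[k] / bursts$value_min[k])
  }))
  structure(list(per_burst = per,
                 mean_rer_pre = mean(per$rer_pre),
                 mean_rer_min = mean(per$rer_min),
                 mean_fold = mean(per$mr_fold)),
            class = "rer_dynamics")
}

#' @export
print.rer_dynamics <- function(x, ...) {
  cat(sprintf(
    "<rer_dynamics> %d bursts: RER %.3f -> %.3f, MR fold-change %.2f\n",
    nrow(x$per_burst), x$mean_rer_pre, x$mean_rer_min, x$mean_fold))
  invisible(x)
}
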