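#' Heat production from oxygen consumption and RER
#'
#' Converts oxygen consumption to oxidative heat production using the mixed
#' carbohydrate/lipid combustion calibration
#' \deqn{HP[mW] = (4.44 + 1.43 \cdot RER) \cdot \dot{V}O_2 [mL\,O_2\,h^{-1}]}
#' Heat production is linear in VO2 and affine (increasing) in RER.
#'
#' @param vo2 Oxygen consumption, mL O2 h^-1 (non-negative; note per *hour* --
#'   multiply per-minute rates by 60).
#' @param rer Respiratory exchange ratio, within \[0.6, 1.1\]; a warning is
#'   issued outside the physiological range \[0.7, 1.0\].
#' @return Heat production in milliwatts, recycled over the longer input.
#' @export
#' @examples
#' heat_production(60, 1.0)   # 352.2 mW
#' heat_production(100, 0.7)  # 544.1 mW
heat_production <- function(vo2, rer) {
  if (any(!is.finite(vo2)) || any(!is.finite(rer)))
    stop("heat_production: inputs must be finite")
  if (any(vo2 < 0))
    stop("heat_production: vo2 must be non-negative")
  if (any(rer < 0.6 | rer > 1.1))
    stop("heat_production: rer outside [0.6, 1.1]")
  if (any(rer < 0.7 | rer > 1.0))
    warning("rer outside the physiological range [0.7, 1.0]")
  (4.44 + 1.43 * rer) * vo2
}

#' Daily energy expenditure of a 24-h record
#'
#' Integrates per-minute heat production over the record. Missing RER samples
#' are filled by the day's centred running-average RER (31-min window), then
#' by the day's mean where still undefined, before conversion. The returned
#' DEE and mean heat production satisfy
#' `dee_kj == mean_hp_mw * seconds / 1e6` exactly, where `seconds` is the
#' record duration.
#'
#' @param day A [physio_day()] with `mr` and `rer` channels, or any object
#'   with numeric `mr` (mL O2 min^-1) and `rer` elements of equal length.
#' @param range Optional integer vector of minute indices (1-based) to
#'   restrict the integration window, e.g. `1:720` for the first 12 h.
#' @return A list with `dee_kj` (kJ per window), `mean_hp_mw` (mW),
#'   `mean_mr` (mL O2 min^-1) and `window_h` (window length, hours).
#' @export
daily_energy <- function(day, range = NULL) {
  if (is.null(day$mr)) stop("daily_energy: MR channel missing")
  if (is.null(day$rer)) stop("daily_energy: RER channel missing")
  mr <- day$mr
  rer <- fill_rer(day$rer)
  if (!is.null(range)) {
    mr <- mr[range]
    rer <- rer[range]
  }
  hp <- heat_production(mr * 60, rer)       # mW per minute sample
  mean_hp <- mean(hp)
  secs <- length(mr) * 60
  list(dee_kj = mean_hp * secs / 1e6,
       mean_hp_mw = mean_hp,
       mean_mr = mean(mr),
       window_h = length(mr) / 60)
}

# Fill missing RER samples with the centred running average, then the mean.
fill_rer <- function(rer, window = 31) {
  if (!anyNA(rer)) return(rer)
  sm <- running_average(ifelse(is.na(rer), mean(rer, na.rm = TRUE), rer),
                        window)
  out <- ifelse(is.na(rer), sm, rer)
  out[is.na(out)] <- mean(rer, na.rm = TRUE)
  out
}

#' Centred running average
#'
#' Centred moving mean that shrinks the window at the series edges, so the
#' output has the same length as the input. For even windows the centre is
#' taken half a step towards the start.
#'
#' @param x Numeric series.
#' @param window Window width in samples (>= 1; not larger than the series).
#' @return Smoothed series of the same length.
#' @export
#' @examples
#' running_average(c(0, 0, 30, 0, 0), 3)
running_average <- function(x, window) {
  window <- as.integer(window)
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window larger than series")
  if (window == 1) return(x)
  left <- ceiling((window - 1) / 2)
  right <- floor((window - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
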