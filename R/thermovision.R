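#' Generate a synthetic 1-s surface-temperature trace for a day
#'
#' Emulates the three measurement areas of an infrared thermovision setup:
#' one trace following the animal, whose short-term (within-minute)
#' variability scales with the injected locomotor activity, and two fixed
#' cage-floor traces near ambient temperature that rise above 30 degrees C
#' while the animal is active outside the nest. By default the outside-nest
#' episodes cluster around the large-class burst peaks of the day's ground
#' truth (feeding and drinking excursions); explicit episodes (whole-minute
#' intervals) can be injected instead.
#'
#' @param config The [synth_config()] the day was generated from.
#' @param day The `physio_day` (supplies the activity channel).
#' @param truth The matching `ground_truth` (supplies large-burst times);
#'   optional when `episodes` is given.
#' @param episodes Optional data.frame with columns `start_min`, `end_min`
#'   (0-based minute of day, half-open) of outside-nest episodes.
#' @return An object of class `tsf_trace`: `seconds` (0..86399),
#'   `hamster_tsf`, `cage_tsf_1`, `cage_tsf_2` (degrees C at 1 s),
#'   `episodes` (the injected episode table), `outside_minutes` (their total
#'   duration).
#' @export
generate_tsf_trace <- function(config, day, truth = NULL, episodes = NULL) {
  act <- day$activity
  if (is.null(act)) stop("day has no activity channel")
  n_min <- length(act)
  n_sec <- n_min * 60L
  if (is.null(episodes)) {
    if (is.null(truth)) stop("either truth or episodes must be supplied")
    ev <- truth$events
    ev <- ev[ev$ur_class == "large", , drop = FALSE]
    if (nrow(ev)) {
      # feeding/drinking excursions cluster around the burst peak; the
      # animal spends most of the burst back in the nest
      span <- round(config$burst_rise[3] / 3)
      st <- pmax(0L, ev$t_peak - span)
      en <- pmin(n_min, ev$t_peak + span)
      o <- order(st)
      st <- st[o]; en <- en[o]
      ms <- st[1]; me <- en[1]
      outs <- list()
      for (i in seq_along(st)[-1]) {
        if (st[i] <= me) me <- max(me, en[i])
        else {
          outs[[length(outs) + 1L]] <- c(ms, me)
          ms <- st[i]; me <- en[i]
        }
      }
      outs[[length(outs) + 1L]] <- c(ms, me)
      m <- do.call(rbind, outs)
      episodes <- data.frame(start_min = m[, 1], end_min = m[, 2])
    } else episodes <- data.frame(start_min = integer(0),
                                  end_min = integer(0))
  }
  outside <- logical(n_min)
  for (i in seq_len(nrow(episodes)))
    outside[seq.int(episodes$start_min[i] + 1L,
                    length.out = episodes$end_min[i] -
                      episodes$start_min[i])] <- TRUE

  with_seed(sub_seed(config$seed, 3L, day$day_index), {
    sd_min <- config$tsf_noise + config$tsf_act_gain * act
    hamster <- 27 + rnorm(n_sec, 0, rep(sd_min, each = 60L))
    cage1 <- config$ta + rnorm(n_sec, 0, 0.1)
    cage2 <- config$ta + rnorm(n_sec, 0, 0.1)
    sec_out <- rep(outside, each = 60L)
    cage1[sec_out] <- 32 + rnorm(sum(sec_out), 0, 0.3)
    clamp <- function(v) pmin(pmax(v, 5), 45)
    structure(list(seconds = 0:(n_sec - 1L),
                   hamster_tsf = clamp(hamster),
                   cage_tsf_1 = clamp(cage1),
                   cage_tsf_2 = clamp(cage2),
                   episodes = episodes,
                   outside_minutes = sum(outside)),
              class = "tsf_trace")
  })
}

#' @export
print.tsf_trace <- function(x, ...) {
  cat(sprintf("<tsf_trace> %d s; %d min outside the nest in %d episodes\n",
              length(x$seconds), x$outside_minutes, nrow(x$episodes)))
  invisible(x)
}

#' Per-minute activity index from a surface-temperature trace
#'
#' Body movements cause short-term surface-temperature changes, so the
#' sample standard deviation of the 1-s animal trace within each minute
#' serves as an index of total activity. An incomplete trailing minute is
#' dropped with a message.
#'
#' @param trace A `tsf_trace`, or a plain numeric 1-s series.
#' @return Numeric vector of per-minute SDs (degrees C).
#' @export
activity_index <- function(trace) {
  x <- if (inherits(trace, "tsf_trace")) trace$hamster_tsf
  else as.numeric(trace)
  n_full <- floor(length(x) / 60L)
  if (n_full * 60L < length(x))
    message("activity_index: dropping incomplete trailing minute (",
            length(x) - n_full * 60L, " samples)")
  m <- matrix(x[seq_len(n_full * 60L)], nrow = 60L)
  apply(m, 2, sd)
}

#' Minutes spent outside the nest from cage-floor traces
#'
#' A minute counts as outside-nest when either fixed cage-floor trace
#' exceeds the threshold for at least `min_samples` of its 60 one-second
#' samples (the warm animal heats the floor it sits on); contiguous
#' outside-nest minutes are merged into episodes.
#'
#' @param trace A `tsf_trace`.
#' @param threshold Surface temperature threshold, degrees C.
#' @param min_samples Minimum number of above-threshold samples per minute.
#' @return A list: `minutes` (total outside-nest minutes), `episodes`
#'   (data.frame `start_min`, `end_min`, half-open 0-based),
#'   `outside` (logical per minute).
#' @export
outside_nest_minutes <- function(trace, threshold = 30, min_samples = 30) {
  n_full <- floor(length(trace$cage_tsf_1) / 60L)
  cnt <- function(v) colSums(matrix(v[seq_len(n_full * 60L)] > threshold,
                                    nrow = 60L))
  outside <- cnt(trace$cage_tsf_1) >= min_samples |
    cnt(trace$cage_tsf_2) >= min_samples
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  ep <- data.frame(start_min = starts[r$values], end_min = ends[r$values])
  list(minutes = sum(outside), episodes = ep, outside = outside)
}

#' Relation between metabolic rate and an activity measure
#'
#' Least-squares slope and Pearson correlation of per-minute MR on a
#' per-minute activity series, computed identically for transmitter counts
#' and for the thermovision activity index so the two methods' slopes can be
#' compared.
#'
#' @param mr Per-minute MR series (or a [physio_day()]).
#' @param activity Aligned per-minute activity series.
#' @return A list: `slope` (MR units per activity unit), `intercept`, `r`,
#'   `p`, `n`.
#' @export
activity_mr_relation <- function(mr, activity) {
  if (inherits(mr, "physio_day")) mr <- mr$mr
  ok <- !is.na(mr) & !is.na(activity)
  mr <- mr[ok]; activity <- activity[ok]
  if (length(mr) != length(activity)) stop("series must be aligned")
  if (sd(activity) == 0) stop("zero-variance activity series")
  fit <- lm(mr ~ activity)
  ct <- cor.test(mr, activity)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(mr))
}
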