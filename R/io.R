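#' Write a physiological day to tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per minute with ISO-8601 timestamps and columns
#' `mr_mlo2_min`, `rer`, `tb_c`, `activity_counts`; record metadata (subject,
#' day index, light phase, ambient temperature) and, optionally, the
#' generator ground truth go into `<stem>.meta.json` next to it.
#'
#' @param day A [physio_day()].
#' @param path CSV file path (the sidecar replaces the extension with
#'   `.meta.json`).
#' @param truth Optional `ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_physio_day <- function(day, path, truth = NULL) {
  utils::write.csv(as.data.frame(day), path, row.names = FALSE)
  meta <- list(subject_id = day$subject_id,
               day_index = day$day_index,
               date = format(day$date),
               light_phase = day$light_phase,
               ta = day$ta)
  if (!is.null(truth))
    meta$ground_truth <- list(
      periods_h = truth$periods_h,
      ultradian_fraction_mr = truth$ultradian_fraction_mr,
      ultradian_fraction_energy = truth$ultradian_fraction_energy,
      events = truth$events)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a physiological day written by [write_physio_day()]
#'
#' @param path CSV file path.
#' @return A [physio_day()]; when the sidecar holds generator ground truth, a
#'   `truth` attribute carries its scalar fields.
#' @export
read_physio_day <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- list(subject_id = "subject-1", day_index = 1L,
               light_phase = c(8, 16), ta = NA_real_,
               date = substr(df$timestamp[1], 1, 10))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (f in c("subject_id", "day_index", "light_phase", "ta", "date"))
      if (!is.null(m[[f]])) meta[[f]] <- m[[f]]
  }
  chan <- function(v) if (all(is.na(v))) NULL else v
  day <- physio_day(mr = chan(df$mr_mlo2_min), rer = chan(df$rer),
                    tb = chan(df$tb_c), activity = chan(df$activity_counts),
                    subject_id = meta$subject_id,
                    day_index = as.integer(meta$day_index),
                    light_phase = as.numeric(meta$light_phase),
                    ta = as.numeric(meta$ta),
                    date = as.Date(meta$date))
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(m$ground_truth)) attr(day, "truth") <- m$ground_truth
  }
  day
}

sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0(".meta.json")
}

#' Write a 1-s surface-temperature trace to CSV
#'
#' Columns: `second`, `hamster_tsf`, `cage1_tsf`, `cage2_tsf`.
#'
#' @param trace A `tsf_trace`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_tsf_trace <- function(trace, path) {
  utils::write.csv(data.frame(second = trace$seconds,
                              hamster_tsf = trace$hamster_tsf,
                              cage1_tsf = trace$cage_tsf_1,
                              cage2_tsf = trace$cage_tsf_2),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a 1-s surface-temperature trace CSV
#'
#' @param path CSV file path with columns `second`, `hamster_tsf`,
#'   `cage1_tsf`, `cage2_tsf`.
#' @return A `tsf_trace` (without episode metadata).
#' @export
read_tsf_trace <- function(path) {
  df <- utils::read.csv(path)
  structure(list(seconds = df$second,
                 hamster_tsf = df$hamster_tsf,
                 cage_tsf_1 = df$cage1_tsf,
                 cage_tsf_2 = df$cage2_tsf,
                 episodes = NULL, outside_minutes = NA_integer_),
            class = "tsf_trace")
}
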