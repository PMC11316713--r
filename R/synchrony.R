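#' Day-by-day ultradian period time-course
#'
#' Collects per-day period estimates into a long table, one row per day x
#' variable x class, the shape consumed by [pairwise_correlations()].
#'
#' @param entries A data.frame with columns `day`, `variable` (e.g. `"mr"`,
#'   `"tb"`, `"activity"`), `class` (`"small"`, `"medium"`, `"large"`) and
#'   `period` (hours; `NA` for undetected), plus an optional `subject_id`.
#' @return The validated data.frame with class `period_timecourse`.
#' @export
period_timecourse <- function(entries) {
  need <- c("day", "variable", "class", "period")
  if (!all(need %in% names(entries)))
    stop("entries must have columns day, variable, class, period")
  ok <- is.na(entries$period) |
    (entries$period >= 0.3 & entries$period <= 6)
  if (!all(ok)) stop("periods must lie within [0.3, 6] h (or be NA)")
  class(entries) <- c("period_timecourse", "data.frame")
  entries
}

#' Pairwise Pearson correlations between ultradian period time-courses
#'
#' Correlates day-by-day period series pairwise: class against class within
#' each variable (`"within_variable"`, e.g. the small-class vs large-class
#' period of metabolic rate across days), and/or variable against variable
#' within each class (`"within_class"`). Days where either member of a pair
#' is undetected are dropped pairwise, never imputed; a comparison with
#' fewer than `min_pairs` complete days is reported with `NA` statistics
#' rather than fabricated.
#'
#' @param tc A [period_timecourse()].
#' @param pairs Which families of comparisons to compute.
#' @param min_pairs Minimum number of complete day-pairs for a correlation.
#' @param alpha Two-sided significance level for the `significant` flag.
#' @return A data.frame of class `synchrony_table`: `family`, `scope`,
#'   `series_a`, `series_b`, `r`, `p`, `n`, `significant`.
#' @export
pairwise_correlations <- function(tc,
                                  pairs = c("within_variable",
                                            "within_class"),
                                  min_pairs = 5, alpha = 0.05) {
  pairs <- match.arg(pairs, several.ok = TRUE)
  rows <- list()
  grab <- function(variable, cls) {
    d <- tc[tc$variable == variable & tc$class == cls, , drop = FALSE]
    d <- d[order(d$day), ]
    stats::setNames(d$period, d$day)
  }
  corr_row <- function(family, scope, la, lb, a, b) {
    days <- intersect(names(a), names(b))
    x <- a[days]; y <- b[days]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(family = family, scope = scope, series_a = la,
                        series_b = lb, r = NA_real_, p = NA_real_,
                        n = n, significant = NA, stringsAsFactors = FALSE))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(family = family, scope = scope, series_a = la, series_b = lb,
               r = unname(ct$estimate), p = ct$p.value, n = n,
               significant = ct$p.value < alpha, stringsAsFactors = FALSE)
  }
  classes <- c("small", "medium", "large")
  vars <- unique(tc$variable)
  if ("within_variable" %in% pairs) {
    for (v in vars)
      for (i in 1:2) for (j in (i + 1):3)
        rows[[length(rows) + 1L]] <-
          corr_row("within_variable", v, classes[i], classes[j],
                   grab(v, classes[i]), grab(v, classes[j]))
  }
  if ("within_class" %in% pairs && length(vars) > 1) {
    vp <- utils::combn(vars, 2)
    for (cl in classes)
      for (k in seq_len(ncol(vp)))
        rows[[length(rows) + 1L]] <-
          corr_row("within_class", cl, vp[1, k], vp[2, k],
                   grab(vp[1, k], cl), grab(vp[2, k], cl))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("synchrony_table", "data.frame")
  out
}

#' Count significant period-synchrony comparisons
#'
#' Aggregates one or several synchrony tables (e.g. across subjects) into
#' the total number of pairwise comparisons, the number significant at the
#' table's alpha, and the percentage (one decimal).
#'
#' @param tables A `synchrony_table`, or a list of them, or (for direct
#'   arithmetic) the significant count when `total` is also given.
#' @param total Optional total count when `tables` is a plain number.
#' @return A list of class `synchrony_summary`: `total`, `significant`,
#'   `percent`.
#' @export
#' @examples
#' synchrony_summary(47, 72)  # 65.3 %
synchrony_summary <- function(tables, total = NULL) {
  if (is.numeric(tables) && !is.null(total)) {
    sig <- tables
    tot <- total
  } else {
    if (inherits(tables, "synchrony_table")) tables <- list(tables)
    tab <- do.call(rbind, tables)
    tot <- nrow(tab)
    sig <- sum(tab$significant, na.rm = TRUE)
  }
  structure(list(total = tot, significant = sig,
                 percent = round(100 * sig / tot, 1)),
            class = "synchrony_summary")
}

#' @export
print.synchrony_summary <- function(x, ...) {
  cat(sprintf("<synchrony_summary> %d of %d comparisons significant (%.1f%%)\n",
              x$significant, x$total, x$percent))
  invisible(x)
}
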