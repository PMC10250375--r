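#' Station peak value for the temperature selection range
#'
#' The mean over the analysis years of each year's maximum daily mean
#' temperature, floored to the nearest 0.5 degC multiple and to zero. Flooring
#' (rather than rounding) guarantees the peak of the selection range is, on
#' average, actually attained by the station record.
#'
#' @param daily A [daily_temperature] object.
#' @param years Integer vector of analysis years.
#' @return Peak value `H` in degC (non-negative multiple of 0.5).
#' @export
station_peak_value <- function(daily, years = complete_years(daily)) {
  years <- intersect(years, complete_years(daily))
  if (length(years) == 0L) abort("no usable (complete) years in the requested range")
  maxima <- vapply(years, function(y) max(year_slice(daily, y), na.rm = TRUE), 0)
  max(0, floor(mean(maxima) / 0.5) * 0.5)
}

#' Self-symmetric selection range of temperature values
#'
#' Builds the palindromic sequence of 0.5 degC multiples rising from 0 degC to
#' the peak value `H` and returning to 0 degC. Values before (and including)
#' the peak carry the `ascending` branch tag and anchor forward from New Year;
#' values after the peak carry `descending` and anchor in reverse from
#' year-end. For `H` in degC the sequence has `4*H + 1` elements.
#'
#' @param H Peak value in degC; non-negative multiple of 0.5.
#' @return Tibble with columns `position`, `value`, `branch`.
#' @export
selection_range <- function(H) {
  if (length(H) != 1L || is.na(H) || H < 0 || abs(H / 0.5 - round(H / 0.5)) > 1e-9) {
    abort("H must be a non-negative multiple of 0.5 degC")
  }
  up <- seq(0, H, by = 0.5)
  down <- rev(up)[-1]
  tibble::tibble(
    position = seq_len(length(up) + length(down)),
    value = c(up, down),
    branch = c(rep("ascending", length(up)), rep("descending", length(down)))
  )
}

#' Forward anchoring date under the five-day pass rule
#'
#' The last day of the first run of five consecutive days whose daily means are
#' all at or above `v`, scanning from the first day of the year. Runs touching
#' missing days are skipped.
#'
#' @param year_temps Numeric vector of length 365 (daily means, degC).
#' @param v Temperature value (degC).
#' @return Day of year (integer) or `NA` if no qualifying run exists.
#' @export
forward_anchor <- function(year_temps, v) {
  stopifnot(length(year_temps) == 365L)
  ok <- !is.na(year_temps) & year_temps >= v
  run5 <- ok[1:361] & ok[2:362] & ok[3:363] & ok[4:364] & ok[5:365]
  d <- which(run5)
  if (length(d) == 0L) NA_integer_ else d[1] + 4L
}

#' Reverse anchoring date under the five-day pass rule
#'
#' Mirror of [forward_anchor()]: days are traversed from December 31 backward
#' and the first run of five consecutive days all at or above `v` is taken.
#' With `rule = "earliest"` (default) the run's calendar-earliest day — the
#' fifth day encountered in reverse order, the strict mirror of the forward
#' rule — is returned; `rule = "latest"` returns the run's calendar-latest day.
#'
#' @inheritParams forward_anchor
#' @param rule Which end of the reverse run to report.
#' @return Day of year (integer) or `NA`.
#' @export
reverse_anchor <- function(year_temps, v, rule = c("earliest", "latest")) {
  rule <- match.arg(rule)
  a <- forward_anchor(rev(year_temps), v)
  if (is.na(a)) return(NA_integer_)
  if (rule == "earliest") 366L - a else 366L - (a - 4L)
}

# anchoring dates for every position of a selection range, one year
anchor_positions <- function(year_temps, value_sequence,
                             reverse_rule = "earliest") {
  vapply(seq_len(nrow(value_sequence)), function(k) {
    v <- value_sequence$value[k]
    if (value_sequence$branch[k] == "ascending") {
      forward_anchor(year_temps, v)
    } else {
      reverse_anchor(year_temps, v, rule = reverse_rule)
    }
  }, integer(1))
}

#' T-linked period for one pair of temperature values in one year
#'
#' @inheritParams forward_anchor
#' @param start_value,end_value Temperature values (degC).
#' @param start_branch,end_branch `"ascending"` (forward anchoring) or
#'   `"descending"` (reverse anchoring).
#' @param reverse_rule Passed to [reverse_anchor()].
#' @return Integer vector `c(start, end)` (both inclusive) or `c(NA, NA)` when
#'   either anchor is missing or the start falls after the end.
#' @export
tlinked_period <- function(year_temps, start_value, end_value,
                           start_branch = "ascending",
                           end_branch = "descending",
                           reverse_rule = "earliest") {
  anchor1 <- if (start_branch == "ascending") forward_anchor(year_temps, start_value)
             else reverse_anchor(year_temps, start_value, reverse_rule)
  anchor2 <- if (end_branch == "ascending") forward_anchor(year_temps, end_value)
             else reverse_anchor(year_temps, end_value, reverse_rule)
  if (is.na(anchor1) || is.na(anchor2) || anchor1 > anchor2) {
    return(c(NA_integer_, NA_integer_))
  }
  c(anchor1, anchor2)
}

# windowed means with the missing-day rule: a year is invalid for a window
# when more than `max_missing` of its days are missing, otherwise the mean is
# taken over the present days.
window_means <- function(year_temps, starts, ends, max_missing = 2L) {
  x <- year_temps
  pres <- !is.na(x)
  x[!pres] <- 0
  cs <- c(0, cumsum(x))
  cn <- c(0, cumsum(pres))
  out <- rep(NA_real_, length(starts))
  valid <- !is.na(starts) & !is.na(ends) & starts <= ends
  s <- starts[valid]; e <- ends[valid]
  n_present <- cn[e + 1L] - cn[s]
  n_missing <- (e - s + 1L) - n_present
  mu <- (cs[e + 1L] - cs[s]) / n_present
  mu[n_missing > max_missing | n_present == 0L] <- NA_real_
  out[valid] <- mu
  out
}

#' Build the batch of T-linked temperature series for a station
#'
#' Constructs the selection range from the station's peak value, anchors every
#' value in every analysis year via the five-day pass rule, pairs all values
#' `i < j` of the selection range, and averages daily mean temperatures over
#' each pair's yearly period. A pair is retained only if its period is valid
#' (both anchors exist, start <= end, and at most `max_missing_days` missing
#' days) in every analysis year, which keeps correlation sample sizes uniform.
#'
#' @param daily A [daily_temperature] object.
#' @param years Analysis years (all must be complete).
#' @param H Peak value; computed with [station_peak_value()] when `NULL`.
#' @param max_missing_days Most missing days tolerated inside a period before
#'   the year is invalid for that pair.
#' @param reverse_rule Passed to [reverse_anchor()].
#' @return A `temperature_batch` object: list with `pairs` (tibble:
#'   `series_id`, `start_pos`, `end_pos`, values, branches, `mean_length`),
#'   `series` (long tibble: `series_id`, `year`, `mean_temp`),
#'   `value_sequence`, `years`, `kind = "tlinked"`.
#' @export
build_tlinked_batch <- function(daily, years, H = NULL, max_missing_days = 2L,
                                reverse_rule = "earliest") {
  years <- sort(intersect(years, complete_years(daily)))
  if (length(years) == 0L) abort("no usable years")
  if (is.null(H)) H <- station_peak_value(daily, years)
  vs <- selection_range(H)
  m <- nrow(vs)
  if (m < 2L) abort("selection range has a single value (H = 0): no pairs can be formed")

  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- tibble::tibble(
    series_id = sprintf("p%03d_%03d", idx[, "row"], idx[, "col"]),
    start_pos = as.integer(idx[, "row"]), end_pos = as.integer(idx[, "col"]),
    start_value = vs$value[idx[, "row"]], end_value = vs$value[idx[, "col"]],
    start_branch = vs$branch[idx[, "row"]], end_branch = vs$branch[idx[, "col"]]
  )

  anchors <- vapply(years, function(y) {
    anchor_positions(year_slice(daily, y), vs, reverse_rule)
  }, integer(m))            # m x n_years
  starts <- anchors[pairs$start_pos, , drop = FALSE]
  ends <- anchors[pairs$end_pos, , drop = FALSE]
  bad_order <- !is.na(starts) & !is.na(ends) & starts > ends
  starts[bad_order] <- NA_integer_; ends[bad_order] <- NA_integer_

  means <- matrix(NA_real_, nrow(pairs), length(years))
  for (k in seq_along(years)) {
    means[, k] <- window_means(year_slice(daily, years[k]),
                               starts[, k], ends[, k], max_missing_days)
  }
  keep <- rowSums(is.na(means)) == 0L
  if (!any(keep)) abort("no T-linked pair has a valid period in every analysis year")

  lengths <- ends - starts + 1L
  pairs$mean_length <- rowMeans(lengths, na.rm = TRUE)
  pairs <- pairs[keep, ]
  series <- tibble::tibble(
    series_id = rep(pairs$series_id, each = length(years)),
    year = rep(years, nrow(pairs)),
    mean_temp = as.vector(t(means[keep, , drop = FALSE]))
  )
  structure(list(pairs = pairs, series = series, value_sequence = vs,
                 years = years, kind = "tlinked", H = H,
                 reverse_rule = reverse_rule),
            class = "temperature_batch")
}

#' @export
print.temperature_batch <- function(x, ...) {
  cat(sprintf("<temperature_batch kind=%s: %d series x %d years%s>\n",
              x$kind, nrow(x$pairs), length(x$years),
              if (!is.null(x$H)) sprintf(", H = %.1f degC", x$H) else ""))
  invisible(x)
}

#' Moving calendar-based comparator batch
#'
#' Fixed calendar windows of widths 15 to 120 days in 3-day steps, slid in
#' 2-day steps between April 1 (DOY 91) and September 30 (DOY 273); daily mean
#' temperatures are averaged within each window year by year. With the default
#' domain this yields 36 widths and 2106 windows. The grid geometry used for
#' tile adjacency is (start index, width index).
#'
#' @inheritParams build_tlinked_batch
#' @param widths Window widths in days.
#' @param doy_range Inclusive day-of-year domain for the windows.
#' @param slide_step Start-date step in days.
#' @return A `temperature_batch` with `kind = "moving_calendar"`; window
#'   metadata in `pairs` (`start_doy`, `width`, `mean_length = width`).
#' @export
moving_calendar_batch <- function(daily, years, widths = seq(15L, 120L, by = 3L),
                                  doy_range = c(91L, 273L), slide_step = 2L,
                                  max_missing_days = 2L) {
  years <- sort(intersect(years, complete_years(daily)))
  if (length(years) == 0L) abort("no usable years")
  grid <- purrr::map_dfr(seq_along(widths), function(wi) {
    w <- widths[wi]
    if (doy_range[1] > doy_range[2] - w + 1L) return(NULL)
    starts <- seq(doy_range[1], doy_range[2] - w + 1L, by = slide_step)
    tibble::tibble(start_doy = as.integer(starts), width = as.integer(w),
                   start_pos = seq_along(starts), end_pos = wi)
  })
  if (nrow(grid) == 0L) {
    grid <- tibble::tibble(start_doy = integer(), width = integer(),
                           start_pos = integer(), end_pos = integer())
  }
  pairs <- dplyr::mutate(grid,
                         series_id = sprintf("w%03d_s%03d", .data$width, .data$start_doy),
                         mean_length = as.numeric(.data$width),
                         .before = 1)
  means <- matrix(NA_real_, nrow(pairs), length(years))
  for (k in seq_along(years)) {
    means[, k] <- window_means(year_slice(daily, years[k]), pairs$start_doy,
                               pairs$start_doy + pairs$width - 1L, max_missing_days)
  }
  keep <- rowSums(is.na(means)) == 0L
  pairs <- pairs[keep, ]
  series <- tibble::tibble(
    series_id = rep(pairs$series_id, each = length(years)),
    year = rep(years, nrow(pairs)),
    mean_temp = as.vector(t(means[keep, , drop = FALSE]))
  )
  structure(list(pairs = pairs, series = series, years = years,
                 kind = "moving_calendar"),
            class = "temperature_batch")
}

#' Calendar-based T-linked comparator batch
#'
#' Freezes each T-linked series onto the calendar: the inter-annually varying
#' start and end dates of its periods are averaged (rounded to the nearest
#' integer day of year) and daily means are then averaged between the two
#' fixed mean dates year by year. Series correspond one-to-one with the
#' T-linked batch.
#'
#' @param batch A T-linked `temperature_batch` from [build_tlinked_batch()].
#' @param daily The [daily_temperature] object the batch was built from.
#' @inheritParams build_tlinked_batch
#' @return A `temperature_batch` with `kind = "calendarized"` and the same
#'   pair geometry as `batch`.
#' @export
calendarized_batch <- function(batch, daily, max_missing_days = 2L) {
  stopifnot(inherits(batch, "temperature_batch"), batch$kind == "tlinked")
  years <- batch$years
  vs <- batch$value_sequence
  anchors <- vapply(years, function(y) {
    anchor_positions(year_slice(daily, y), vs, batch$reverse_rule)
  }, integer(nrow(vs)))
  pairs <- batch$pairs
  st <- anchors[pairs$start_pos, , drop = FALSE]
  en <- anchors[pairs$end_pos, , drop = FALSE]
  bad <- !is.na(st) & !is.na(en) & st > en
  st[bad] <- NA_integer_; en[bad] <- NA_integer_
  pairs$start_doy <- as.integer(round(rowMeans(st, na.rm = TRUE)))
  pairs$end_doy <- as.integer(round(rowMeans(en, na.rm = TRUE)))
  pairs$mean_length <- as.numeric(pairs$end_doy - pairs$start_doy + 1L)
  means <- matrix(NA_real_, nrow(pairs), length(years))
  for (k in seq_along(years)) {
    means[, k] <- window_means(year_slice(daily, years[k]), pairs$start_doy,
                               pairs$end_doy, max_missing_days)
  }
  series <- tibble::tibble(
    series_id = rep(pairs$series_id, each = length(years)),
    year = rep(years, nrow(pairs)),
    mean_temp = as.vector(t(means))
  )
  structure(list(pairs = pairs, series = series, value_sequence = vs,
                 years = years, kind = "calendarized", H = batch$H),
            class = "temperature_batch")
}

#' Export a temperature batch as long and wide tables
#'
#' @param batch A `temperature_batch`.
#' @return The long series tibble joined with pair metadata.
#' @export
batch_table <- function(batch) {
  dplyr::left_join(batch$series, batch$pairs, by = "series_id")
}

# batch series as a years x series matrix for fast correlation
batch_matrix <- function(batch) {
  wide <- tidyr::pivot_wider(batch$series, id_cols = "year",
                             names_from = "series_id", values_from = "mean_temp")
  wide <- dplyr::arrange(wide, .data$year)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$year
  m
}
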