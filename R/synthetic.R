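#' Generate a synthetic boreal daily temperature record
#'
#' Emulates the main features of boreal station records that the T-linked
#' method exploits: a strong annual cycle, autocorrelated daily noise, and —
#' crucially — inter-annually jittered season timing, so the calendar dates at
#' which given temperature values are reached move from year to year.
#' `value(d) = level + amplitude * cos(2*pi*(d - peak_d) / 365) + AR(1) noise`,
#' with `peak_d = peak_doy + N(0, jitter_sd)` drawn once per year.
#'
#' @param years Integer vector of years to simulate.
#' @param level Mean annual temperature level (degC).
#' @param amplitude Seasonal half-range (degC, > 0).
#' @param peak_doy Day of year of the average summer peak.
#' @param jitter_sd SD (days) of the per-year peak-timing jitter.
#' @param noise_sd SD (degC) of the daily AR(1) noise innovations.
#' @param ar1 AR(1) coefficient of the daily noise.
#' @param seed Integer seed; all randomness is local to the call.
#' @param station_id,latitude,longitude Station metadata.
#' @return A [daily_temperature] object. Attribute `peak_days` records the
#'   jittered per-year peak day (the planted timing truth).
#' @export
gen_daily_temperature <- function(years, level = -5, amplitude = 20,
                                  peak_doy = 200, jitter_sd = 0,
                                  noise_sd = 0, ar1 = 0.6, seed = 1L,
                                  station_id = "SYN001", latitude = 60,
                                  longitude = 100) {
  stopifnot(amplitude > 0, jitter_sd >= 0, noise_sd >= 0)
  withr::with_seed(seed, {
    peaks <- peak_doy + rnorm(length(years), 0, jitter_sd)
    vals <- purrr::map_dfr(seq_along(years), function(k) {
      d <- 1:365
      mu <- level + amplitude * cos(2 * pi * (d - peaks[k]) / 365)
      eps <- if (noise_sd > 0) {
        as.numeric(stats::filter(rnorm(365, 0, noise_sd), ar1,
                                 method = "recursive"))
      } else rep(0, 365)
      tibble::tibble(year = years[k], doy = d, tavg_c = mu + eps)
    })
  })
  out <- daily_temperature(vals, station_id, latitude, longitude)
  attr(out, "peak_days") <- setNames(peaks, years)
  out
}

#' Generate a ring-width network with a planted T-linked response
#'
#' Builds one population of trees whose annual growth index is driven by the
#' mean temperature over a chosen T-linked window of the supplied daily record:
#' `index = 1 + beta * z(Tbar) + noise`, where `z` standardizes the yearly
#' window means (so `beta` is unit-free across stations) and `Tbar` is computed
#' with the same five-day anchoring rules used by the analysis. The index is
#' modulated by a negative-exponential age curve into widths (mm).
#'
#' @param daily A [daily_temperature] object (truth source for the window).
#' @param years Years to simulate growth for.
#' @param start_value,end_value Planted window temperature values (degC).
#' @param start_branch,end_branch Branch tags of the planted pair.
#' @param beta Signed response coefficient (index units per SD of window
#'   temperature); 0 plants no response.
#' @param noise_sd SD of the white noise added to the index.
#' @param n_trees Trees in the population.
#' @param series_per_tree Ring-width series (cores) per tree.
#' @param age_curve `c(a, k, b)` of the width modulation
#'   `a * exp(-k * age) + b` (mm).
#' @param population_id Population tag.
#' @param seed Integer seed.
#' @return Long tibble: `series_id`, `tree_id`, `population_id`, `year`,
#'   `width_mm`; attribute `window_means` holds the planted yearly `Tbar`.
#' @export
gen_growth_network <- function(daily, years, start_value = 5, end_value = 5,
                               start_branch = "ascending",
                               end_branch = "descending", beta = 0.5,
                               noise_sd = 0.2, n_trees = 25L,
                               series_per_tree = 1L,
                               age_curve = c(1.5, 0.02, 0.5),
                               population_id = "POP01", seed = 1L) {
  years <- sort(intersect(years, complete_years(daily)))
  tbar <- vapply(years, function(y) {
    temps <- year_slice(daily, y)
    per <- tlinked_period(temps, start_value, end_value, start_branch, end_branch)
    if (is.na(per[1])) return(NA_real_)
    mean(temps[per[1]:per[2]], na.rm = TRUE)
  }, 0)
  if (anyNA(tbar)) abort("planted window is invalid in some years; choose lower values")
  z <- as.numeric(scale(tbar))
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_trees), function(tr) {
      purrr::map_dfr(seq_len(series_per_tree), function(cc) {
        idx <- 1 + beta * z + rnorm(length(years), 0, noise_sd)
        age <- seq_along(years)
        width <- pmax(idx, 0.05) * (age_curve[1] * exp(-age_curve[2] * age) +
                                      age_curve[3])
        tibble::tibble(
          series_id = sprintf("%s_T%02dC%d", population_id, tr, cc),
          tree_id = sprintf("%s_T%02d", population_id, tr),
          population_id = population_id, year = years, width_mm = width)
      })
    })
  })
  structure(out, window_means = setNames(tbar, years))
}

#' Generate labelled climate observations from the logistic model
#'
#' Draws (MAT, MAP) uniformly over the given ranges and labels each point
#' `negative` with probability `P = 1/(1 + exp(w1*MAT + w2*MAP + w3))` —
#' ground truth for boundary-model fitting and validation.
#'
#' @param w1,w2,w3 Model coefficients (plus-exponent convention).
#' @param n Number of observations.
#' @param mat_range,map_range Uniform sampling ranges for MAT (degC) and
#'   MAP (mm).
#' @param seed Integer seed.
#' @return Tibble with `MAT`, `MAP`, `group` (`"negative"`/`"positive"`) and
#'   the true `probability`.
#' @export
gen_logistic_observations <- function(w1, w2, w3, n = 2000L,
                                      mat_range = c(-15, 5),
                                      map_range = c(150, 900), seed = 1L) {
  withr::with_seed(seed, {
    MAT <- runif(n, mat_range[1], mat_range[2])
    MAP <- runif(n, map_range[1], map_range[2])
    p <- 1 / (1 + exp(w1 * MAT + w2 * MAP + w3))
    g <- rbinom(n, 1L, p)
  })
  tibble::tibble(MAT = MAT, MAP = MAP,
                 group = ifelse(g == 1L, "negative", "positive"),
                 probability = p)
}

#' Published larch boundary-model coefficients
#'
#' Reference parameter estimates of the negative-response logistic model for
#' the two boreal larch species, in the plus-exponent convention
#' (`P = 1/(1 + exp(w1*MAT + w2*MAP + w3))`).
#'
#' @return Named list of two [boundary_model] objects,
#'   `siberian_larch` and `dahurian_larch`.
#' @export
larch_reference_models <- function() {
  list(
    siberian_larch = boundary_model(w1 = -0.5974, w2 = 0.01212, w3 = -7.3368,
                                    species = "siberian_larch"),
    dahurian_larch = boundary_model(w1 = -0.7363, w2 = 0.01737, w3 = -14.0796,
                                    species = "dahurian_larch")
  )
}
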