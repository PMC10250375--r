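# shared fixtures and independent oracles

# daily_temperature object from a per-year 365-day value function
make_daily <- function(years, fun, station_id = "FIX", lat = 60, lon = 100) {
  vals <- purrr::map_dfr(years, function(y) {
    tibble::tibble(year = y, doy = 1:365, tavg_c = fun(y))
  })
  daily_temperature(vals, station_id, lat, lon)
}

# smooth sinusoidal year: warm mid-season, cold winters
sinusoid_year <- function(level = -5, amplitude = 20, peak = 200) {
  level + amplitude * cos(2 * pi * ((1:365) - peak) / 365)
}

# brute-force five-day-run scanners (independent of the implementation)
brute_forward <- function(temps, v) {
  ok <- !is.na(temps) & temps >= v
  for (d in 5:365) if (all(ok[(d - 4):d])) return(d)
  NA_integer_
}
brute_reverse <- function(temps, v, rule = "earliest") {
  ok <- !is.na(temps) & temps >= v
  for (d in 361:1) {
    if (all(ok[d:(d + 4)])) {
      return(if (rule == "earliest") d else d + 4L)
    }
  }
  NA_integer_
}

# hand-built correlation grid for metric tests
make_grid <- function(start_pos, end_pos, r, p, mean_length = 30, n = 31) {
  g <- tibble::tibble(series_id = sprintf("t%03d", seq_along(start_pos)),
                      start_pos = as.integer(start_pos),
                      end_pos = as.integer(end_pos),
                      mean_length = rep_len(mean_length, length(start_pos)),
                      r = r, p = p, n = n)
  structure(g, class = c("correlation_grid", class(g)))
}

# ray-casting point-in-polygon oracle (closed polygon matrix)
pip_oracle <- function(poly, x, y) {
  n <- nrow(poly) - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((poly[i, 2] > y) != (poly[j, 2] > y)) &&
        (x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# haversine great-circle distance oracle (km)
hav_oracle <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6378.137 * asin(pmin(1, sqrt(a)))
}
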