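#' Daily mean temperature series
#'
#' A `daily_temperature` object is a tibble with one row per (year, day-of-year)
#' holding daily mean temperatures for a single station, after leap-day
#' normalization: February 29 is dropped and the remaining days renumbered so
#' every year has exactly 365 days. Missing days are present as `NA` rows, so a
#' complete year always spans `doy` 1..365.
#'
#' @param values A data frame with columns `year`, `doy`, `tavg_c`.
#' @param station_id Station identifier.
#' @param latitude,longitude Station coordinates in decimal degrees.
#' @return A tibble of class `daily_temperature` with columns
#'   `station_id`, `year`, `doy`, `tavg_c`, and attributes `latitude`,
#'   `longitude`, `incomplete_years` (years with more than 10% of days missing).
#' @export
daily_temperature <- function(values, station_id, latitude = NA_real_,
                              longitude = NA_real_) {
  stopifnot(all(c("year", "doy", "tavg_c") %in% names(values)))
  if (any(values$doy < 1 | values$doy > 365, na.rm = TRUE)) {
    abort("day-of-year must lie in [1, 365] after leap-day normalization")
  }
  bad <- is.finite(values$tavg_c) & (values$tavg_c < -80 | values$tavg_c > 50)
  if (any(bad)) {
    abort(sprintf("%d daily values outside the plausible range [-80, 50] degC",
                  sum(bad)))
  }
  grid <- tidyr::expand_grid(year = sort(unique(values$year)), doy = 1:365)
  out <- dplyr::left_join(grid, values[, c("year", "doy", "tavg_c")],
                          by = c("year", "doy"))
  out <- tibble::as_tibble(dplyr::mutate(out, station_id = station_id,
                                         .before = 1))
  n_missing <- tapply(is.na(out$tavg_c), out$year, sum)
  incomplete <- as.integer(names(n_missing))[n_missing > 0.10 * 365]
  structure(out,
            latitude = latitude, longitude = longitude,
            incomplete_years = incomplete,
            class = c("daily_temperature", class(out)))
}

#' Read a daily station temperature record
#'
#' Reads GHCN-Daily style CSV (`STATION,DATE,TAVG`, temperatures in tenths of a
#' degree Celsius; optional `LATITUDE`/`LONGITUDE` columns) or a plain long CSV
#' (`station,date,tavg_c` in whole degrees). Dates are calendar-indexed,
#' February 29 is dropped and days renumbered 1..365, and missing days are kept
#' as `NA`. Years with more than 10% of days missing are flagged incomplete.
#'
#' @param path Path to the CSV file.
#' @param dialect `"ghcn_csv"` (tenths of degC) or `"long_csv"` (degC).
#' @return A [daily_temperature] tibble.
#' @export
read_daily_temperature <- function(path, dialect = c("ghcn_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if (dialect == "ghcn_csv") {
    need <- c("station", "date", "tavg")
    scale <- 0.1
  } else {
    need <- c("station", "date", "tavg_c")
    scale <- 1
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("missing column(s) %s for dialect '%s'",
                  paste(miss, collapse = ", "), dialect))
  }
  date <- as.Date(as.character(df[[need[2]]]), tryFormats = c("%Y-%m-%d", "%Y%m%d"))
  if (anyNA(date)) {
    abort(sprintf("unparseable date at line %d of %s",
                  which(is.na(date))[1] + 1L, path))
  }
  tavg <- suppressWarnings(as.numeric(df[[need[3]]])) * scale
  bad <- which(!is.na(df[[need[3]]]) & is.na(tavg))
  if (length(bad)) {
    abort(sprintf("unparseable temperature at line %d of %s", bad[1] + 1L, path))
  }
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  dy <- as.integer(format(date, "%d"))
  keep <- !(mo == 2 & dy == 29)
  values <- tibble::tibble(year = yr[keep],
                           doy = doy_365(mo[keep], dy[keep]),
                           tavg_c = tavg[keep])
  lat <- if ("latitude" %in% names(df)) df$latitude[1] else NA_real_
  lon <- if ("longitude" %in% names(df)) df$longitude[1] else NA_real_
  daily_temperature(values, station_id = as.character(df[[need[1]]][1]),
                    latitude = lat, longitude = lon)
}

# day-of-year on the fixed 365-day calendar (Feb 29 already removed)
doy_365 <- function(month, day) {
  cum <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
  cum[month] + day
}

#' Years with at most 10% of daily values missing
#' @param daily A [daily_temperature] object.
#' @return Integer vector of usable years.
#' @export
complete_years <- function(daily) {
  setdiff(sort(unique(daily$year)), attr(daily, "incomplete_years"))
}

#' Extract one year as an ordered day-of-year sequence
#'
#' @param daily A [daily_temperature] object.
#' @param year Year to extract; must lie inside the series' year range.
#' @param allow_incomplete Return incomplete years (more than 10% of days
#'   missing) instead of erroring.
#' @return Numeric vector of length 365 (daily means, degC) with `NA` for
#'   missing days.
#' @export
year_slice <- function(daily, year, allow_incomplete = FALSE) {
  if (!year %in% daily$year) {
    abort(sprintf("year %d is outside the series range %d..%d", year,
                  min(daily$year), max(daily$year)))
  }
  if (!allow_incomplete && year %in% attr(daily, "incomplete_years")) {
    abort(sprintf("year %d has >10%% of days missing; pass allow_incomplete = TRUE", year))
  }
  x <- daily$tavg_c[daily$year == year]
  stopifnot(length(x) == 365L)
  x
}

#' Match populations to their nearest meteorological station
#'
#' Assigns each population the station minimizing great-circle (haversine)
#' distance; ties are broken by the lexicographically smaller station id.
#'
#' @param populations Data frame with columns `population_id`, `latitude`,
#'   `longitude` (and any others, carried through).
#' @param stations Either a list of [daily_temperature] objects or a data frame
#'   with columns `station_id`, `latitude`, `longitude`.
#' @return `populations` with columns `station_id` and `station_distance_km`
#'   appended.
#' @export
match_station <- function(populations, stations) {
  if (is.data.frame(stations)) {
    st <- stations
  } else {
    st <- purrr::map_dfr(stations, function(s) {
      tibble::tibble(station_id = s$station_id[1],
                     latitude = attr(s, "latitude"),
                     longitude = attr(s, "longitude"))
    })
  }
  if (nrow(st) == 0L) abort("no stations supplied")
  st <- dplyr::arrange(st, .data$station_id)
  d <- geosphere::distm(cbind(populations$longitude, populations$latitude),
                        cbind(st$longitude, st$latitude),
                        fun = geosphere::distHaversine)
  idx <- apply(d, 1L, which.min)  # first minimum = smaller id after sort
  dplyr::mutate(tibble::as_tibble(populations),
                station_id = st$station_id[idx],
                station_distance_km = d[cbind(seq_len(nrow(populations)), idx)] / 1000)
}

#' Gridded climate layer (MAT or MAP)
#'
#' In-memory raster of a long-term climate normal or projection: a numeric
#' matrix (row 1 = northernmost row) plus a geotransform, read and written in
#' the plain-text ESRI ASCII grid format.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell size in degrees.
#' @param variable `"MAT"` (degC) or `"MAP"` (mm).
#' @param period_label,scenario_label,model_label Optional provenance labels
#'   (e.g. `"1970-2000"`, `"ssp245"`, a GCM name).
#' @return A `climate_grid` object.
#' @export
climate_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                         variable = c("MAT", "MAP"), period_label = NA_character_,
                         scenario_label = NA_character_, model_label = NA_character_) {
  variable <- match.arg(variable)
  values <- as.matrix(values)
  if (variable == "MAT" && any(values < -40 | values > 40, na.rm = TRUE)) {
    abort("MAT cells must lie in [-40, 40] degC")
  }
  if (variable == "MAP" && any(values < 0, na.rm = TRUE)) {
    abort("MAP cells must be non-negative")
  }
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 variable = variable, period_label = period_label,
                 scenario_label = scenario_label, model_label = model_label),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid %s %dx%d cells, cellsize %g, origin (%g, %g)%s>\n",
              x$variable, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll,
              if (is.na(x$period_label)) "" else paste0(", ", x$period_label)))
  invisible(x)
}

#' Read a climate grid from an ESRI ASCII raster
#'
#' @param path Path to an `.asc` file (single band by construction).
#' @param variable `"MAT"` or `"MAP"`.
#' @inheritParams climate_grid
#' @return A [climate_grid] object with nodata cells mapped to `NA`.
#' @export
read_climate_grid <- function(path, variable = c("MAT", "MAP"),
                              period_label = NA_character_,
                              scenario_label = NA_character_,
                              model_label = NA_character_) {
  variable <- match.arg(variable)
  stopifnot(file.exists(path))
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("'%s' is not an ESRI ASCII grid (missing header keys)", path))
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("grid body has %d values, expected %d (multi-band rasters are not supported)",
                  length(vals), hdr$ncols * hdr$nrows))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  climate_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
               cellsize = hdr$cellsize, variable = variable,
               period_label = period_label, scenario_label = scenario_label,
               model_label = model_label)
}

#' Write a climate grid as an ESRI ASCII raster
#'
#' @param grid A [climate_grid] object.
#' @param path Output path.
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_climate_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$xll), sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Check that paired MAT/MAP layers are aligned
#'
#' @param mat,map [climate_grid] objects.
#' @return `TRUE`, invisibly; errors when shapes or geotransforms differ.
#' @export
check_grid_pair <- function(mat, map) {
  if (!identical(dim(mat$values), dim(map$values))) {
    abort("MAT and MAP grids have different shapes")
  }
  if (!isTRUE(all.equal(c(mat$xll, mat$yll, mat$cellsize),
                        c(map$xll, map$yll, map$cellsize)))) {
    abort("MAT and MAP grids have different geotransforms")
  }
  invisible(TRUE)
}

#' Read a population metadata table
#'
#' @param path CSV with columns `population_id`, `species`, `latitude`,
#'   `longitude`.
#' @return A tibble; species coerced to factor
#'   `{siberian_larch, dahurian_larch}`; coordinates checked against plausible
#'   boreal Eurasian bounds.
#' @export
read_population_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("population_id", "species", "latitude", "longitude")
  stopifnot(all(need %in% names(df)))
  if (any(df$latitude < 40 | df$latitude > 80)) {
    abort("population latitude outside plausible bounds (40-80 degrees N)")
  }
  ok <- df$species %in% c("siberian_larch", "dahurian_larch")
  if (!all(ok)) abort("species must be siberian_larch or dahurian_larch")
  tibble::as_tibble(df)
}
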