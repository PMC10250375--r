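#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the classic decadal layout: series id (cols 1-8), decade start year,
#' then up to ten width values per line. Stop markers `999` (units mm x 100)
#' and `-9999` (mm x 1000) terminate a series and set its unit dialect, which
#' is autodetected per series.
#'
#' @param path Path to the `.rwl` file.
#' @return Long tibble: `series_id`, `year`, `width_mm` (widths > 0).
#' @export
read_rwl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    id <- trimws(substr(ln, 1, 8))
    rest <- strsplit(trimws(substr(ln, 9, nchar(ln))), "\\s+")[[1]]
    if (length(rest) < 2L) abort(sprintf("unparseable RWL line %d", i))
    year0 <- suppressWarnings(as.integer(rest[1]))
    vals <- suppressWarnings(as.numeric(rest[-1]))
    if (is.na(year0) || anyNA(vals)) abort(sprintf("unparseable RWL line %d", i))
    out[[i]] <- tibble::tibble(series_id = id,
                               year = year0 + seq_along(vals) - 1L,
                               raw = vals)
  }
  df <- dplyr::bind_rows(out)
  purrr::map_dfr(split(df, df$series_id), function(s) {
    stop_val <- s$raw[nrow(s)]
    divisor <- if (isTRUE(all.equal(stop_val, -9999))) 1000 else 100
    s <- s[s$raw != 999 & s$raw != -9999, ]
    tibble::tibble(series_id = s$series_id, year = s$year,
                   width_mm = s$raw / divisor)
  })
}

#' Write ring widths in Tucson/RWL decadal format
#'
#' @param rwl Long tibble with `series_id`, `year`, `width_mm`.
#' @param path Output path.
#' @param units `"mm100"` (stop marker 999) or `"mm1000"` (stop marker -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path, units = c("mm100", "mm1000")) {
  units <- match.arg(units)
  mult <- if (units == "mm100") 100 else 1000
  stop_val <- if (units == "mm100") 999 else -9999
  con <- file(path, "w")
  on.exit(close(con))
  for (s in split(rwl, rwl$series_id)) {
    s <- s[order(s$year), ]
    vals <- c(round(s$width_mm * mult), stop_val)
    yrs <- c(s$year, max(s$year) + 1L)
    k <- 1L
    while (k <= length(vals)) {
      decade_end <- (yrs[k] %/% 10L) * 10L + 9L
      take <- which(yrs >= yrs[k] & yrs <= decade_end & seq_along(yrs) >= k)
      writeLines(sprintf("%-8s%4d%s", s$series_id[1], yrs[k],
                         paste(sprintf("%6d", vals[take]), collapse = "")), con)
      k <- max(take) + 1L
    }
  }
  invisible(path)
}

#' Data-adaptive power transformation exponent
#'
#' Estimates the exponent `p = 1 - b`, where `b` is the slope of the log-log
#' regression of the local spread proxy `|x_t - x_(t-1)|` on the local level
#' `(x_t + x_(t-1))/2`. For a homoscedastic series `p` is near 1 (no
#' transform); when spread is proportional to level `p` is near 0 and a log
#' transform is indicated.
#'
#' @param x Positive numeric series (>= 10 values).
#' @return Exponent `p`.
#' @export
power_transform_exponent <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 10L, all(x > 0))
  spread <- abs(diff(x))
  level <- (x[-1] + x[-length(x)]) / 2
  keep <- spread > 0
  if (sum(keep) < 3L) {
    warn("series is (near-)constant; identity transform used")
    return(1)
  }
  b <- coef(lm(log(spread[keep]) ~ log(level[keep])))[[2]]
  1 - b
}

#' Data-adaptive power transformation
#'
#' Applies `x^p` with `p` from [power_transform_exponent()]; a natural log is
#' used when `|p| < 0.05`. Stabilizes variance prior to difference detrending.
#'
#' @param x Positive numeric series.
#' @return Numeric series with attribute `exponent`.
#' @export
power_transform <- function(x) {
  p <- power_transform_exponent(x)
  out <- if (abs(p) < 0.05) log(x) else x^p
  structure(out, exponent = p)
}

# smoothing parameter for the penalized second-difference smoother whose
# frequency response 1/(1 + lambda*(2 - 2 cos w)^2) equals `response` at
# period `cutoff` (years); the discrete analogue of the classic
# frequency-cutoff cubic smoothing spline.
spline_lambda <- function(cutoff, response = 0.5) {
  w <- 2 * pi / cutoff
  (1 / response - 1) / (2 - 2 * cos(w))^2
}

#' Frequency-cutoff smoothing spline
#'
#' Fits the discrete cubic smoothing spline (penalized second differences) to
#' an annual series, with the smoothing parameter chosen so the smoother's
#' amplitude frequency response equals 50% at the cutoff period: variance at
#' periods longer than the cutoff is mostly assigned to the fitted curve,
#' variance at shorter periods mostly survives detrending.
#'
#' @param x Numeric series (no internal `NA`s).
#' @param cutoff Cutoff period in years at which the response is 0.5.
#' @return Fitted smooth curve, same length as `x`.
#' @export
ff_spline <- function(x, cutoff = 30) {
  n <- length(x)
  stopifnot(n >= 4L, !anyNA(x))
  lambda <- spline_lambda(cutoff)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, x))
}

#' Detrend a ring-width series with a frequency-cutoff spline
#'
#' Removes the age/size-related low-frequency growth trend by fitting
#' [ff_spline()] and either dividing by the fitted curve (`ratio`, the default,
#' yielding a dimensionless index with mean near 1) or subtracting it
#' (`difference`, used where ratios misbehave; pair with [power_transform()]).
#' If any fitted value is non-positive in ratio mode the series is switched to
#' difference mode with a warning (the classic end-effects remedy), with the
#' difference index re-centred on 1.
#'
#' @param x Numeric ring-width series (positive, no internal `NA`s).
#' @param cutoff Spline cutoff period in years (default 30; a series-relative
#'   alternative such as 67% of the series length can be passed explicitly).
#' @param mode `"ratio"` or `"difference"`.
#' @return Growth index series with attributes `detrend_mode` and `fitted`.
#' @export
spline_detrend <- function(x, cutoff = 30, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= cutoff / 2)
  fit <- ff_spline(x, cutoff)
  if (mode == "ratio" && any(fit <= 0)) {
    warn("non-positive fitted values; switching to difference detrending")
    mode <- "difference"
  }
  idx <- if (mode == "ratio") x / fit else x - fit + 1
  structure(idx, detrend_mode = mode, fitted = fit)
}

#' Prewhiten a growth index with an autoregressive model
#'
#' Fits an AR model (order selected by AIC in `0..max_order`, Yule-Walker
#' estimation) and keeps the residuals, re-centred on the input mean so
#' chronologies remain near 1. The initial `order` years lost to conditioning
#' are dropped.
#'
#' @param x Growth index series (>= 20 values, no internal `NA`s).
#' @param max_order Maximum AR order considered.
#' @return Residual series (length `length(x) - order`) with attribute
#'   `ar_order`; years trimmed from the front.
#' @export
prewhiten <- function(x, max_order = 5L) {
  stopifnot(length(x) >= 20L, !anyNA(x))
  fit <- tryCatch(ar(x, aic = TRUE, order.max = max_order, method = "yule-walker"),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warn("AR fit failed; passing series through unwhitened (order 0)")
    return(structure(x, ar_order = 0L))
  }
  if (fit$order == 0L) return(structure(x, ar_order = 0L))
  res <- fit$resid[!is.na(fit$resid)]
  structure(res - mean(res) + mean(x), ar_order = fit$order)
}

#' Standardize a long ring-width table into growth indices
#'
#' Runs the per-series standardization chain — optional adaptive power
#' transformation, frequency-cutoff spline detrending, optional AR
#' prewhitening — over a long ring-width table.
#'
#' @param rwl Long tibble: `series_id`, `year`, `width_mm`, plus optional
#'   `tree_id` / `population_id` carried through.
#' @param cutoff Spline cutoff period in years.
#' @param mode `"ratio"` or `"difference"` detrending.
#' @param transform Apply the adaptive power transformation first (intended
#'   for difference detrending).
#' @param prewhiten Remove autocorrelation from the detrended index.
#' @param max_order Maximum AR order for prewhitening.
#' @return Long tibble of growth indices: key columns plus `year`, `index`.
#' @export
standardize_rwl <- function(rwl, cutoff = 30, mode = c("ratio", "difference"),
                            transform = FALSE, prewhiten = TRUE,
                            max_order = 5L) {
  mode <- match.arg(mode)
  keys <- intersect(c("series_id", "tree_id", "population_id"), names(rwl))
  purrr::map_dfr(split(rwl, rwl$series_id), function(s) {
    s <- s[order(s$year), ]
    x <- s$width_mm
    if (transform) x <- as.numeric(power_transform(x))
    idx <- spline_detrend(x, cutoff = cutoff, mode = mode)
    yrs <- s$year
    if (prewhiten && length(idx) >= 20L) {
      res <- prewhiten(as.numeric(idx), max_order = max_order)
      yrs <- yrs[(length(idx) - length(res) + 1L):length(idx)]
      idx <- res
    }
    dplyr::bind_cols(s[match(yrs, s$year), keys, drop = FALSE],
                     tibble::tibble(year = yrs, index = as.numeric(idx)))
  })
}

#' Tree chronology: arithmetic per-year mean of a tree's growth series
#'
#' @param growth Long tibble with `tree_id`, `year`, `index`.
#' @return Tibble `tree_id`, `year`, `index`, `sample_depth`.
#' @export
tree_chronology <- function(growth) {
  dplyr::summarise(dplyr::group_by(growth, .data$tree_id, .data$year),
                   sample_depth = sum(!is.na(.data$index)),
                   index = mean(.data$index, na.rm = TRUE),
                   .groups = "drop")
}

#' Tukey biweight robust mean
#'
#' One-step biweight estimate starting from the median and the median absolute
#' deviation (unscaled), with tuning constant `c`. Values further than `c` MADs
#' from the median receive zero weight. A zero MAD returns the median.
#'
#' @param x Numeric values.
#' @param c Tuning constant (default 9, the dendrochronology convention).
#' @return The robust mean.
#' @export
biweight_mean <- function(x, c = 9) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- median(x)
  s <- median(abs(x - m))
  if (s == 0) return(m)
  u <- (x - m) / (c * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Population chronology: biweight per-year mean over all growth series
#'
#' @param growth Long tibble with `population_id`, `year`, `index`.
#' @return Tibble `population_id`, `year`, `index`, `sample_depth`; years with
#'   zero sample depth are absent.
#' @export
population_chronology <- function(growth) {
  dplyr::summarise(dplyr::group_by(growth, .data$population_id, .data$year),
                   sample_depth = sum(!is.na(.data$index)),
                   index = biweight_mean(.data$index),
                   .groups = "drop")
}

#' Filter growth series by coverage inside an analysis window
#'
#' Keeps only series with at least `min_years` non-missing years inside the
#' window, the coverage rule applied before correlation analysis.
#'
#' @param growth Long tibble with `series_id`, `year`, `index`.
#' @param window Inclusive year range `c(first, last)`.
#' @param min_years Minimum number of years (default 25).
#' @return The filtered tibble (rows restricted to the window).
#' @export
filter_series <- function(growth, window, min_years = 25L) {
  g <- growth[growth$year >= window[1] & growth$year <= window[2] &
                !is.na(growth$index), ]
  counts <- table(g$series_id)
  keep <- names(counts)[counts >= min_years]
  g[g$series_id %in% keep, ]
}
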