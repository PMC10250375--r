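#' Correlate a growth series with a temperature batch
#'
#' Pearson correlation of an annual growth index with every series of a
#' temperature batch over an analysis window, giving one tile per series on
#' the batch's pair grid. Tiles with fewer than `min_years` overlapping years
#' are dropped.
#'
#' @param growth Tibble with `year` and `index` (a standardized growth series
#'   or a population chronology).
#' @param batch A `temperature_batch`.
#' @param window Inclusive year range `c(first, last)`; defaults to the batch
#'   years.
#' @param min_years Minimum overlap (default 25).
#' @return A `correlation_grid`: tibble `series_id`, `start_pos`, `end_pos`,
#'   `mean_length`, `r`, `p`, `n`, with the batch kind as an attribute.
#' @export
correlate <- function(growth, batch, window = range(batch$years),
                      min_years = 25L) {
  g <- growth[growth$year >= window[1] & growth$year <= window[2], ]
  tm <- batch_matrix(batch)
  yrs <- intersect(as.integer(rownames(tm)), g$year[!is.na(g$index)])
  gv <- g$index[match(yrs, g$year)]
  tm <- tm[match(yrs, as.integer(rownames(tm))), , drop = FALSE]
  n <- length(yrs)
  if (n < min_years) abort(sprintf("only %d overlapping years (< %d)", n, min_years))
  # constant temperature series have no defined correlation; dropped below
  r <- as.numeric(suppressWarnings(cor(gv, tm)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- dplyr::mutate(
    batch$pairs[, intersect(c("series_id", "start_pos", "end_pos", "mean_length"),
                            names(batch$pairs))],
    r = r, p = p, n = n)
  out <- out[!is.na(out$r), ]
  if (nrow(out) == 0L) abort("no pair retained: all temperature series are degenerate")
  structure(out, kind = batch$kind, class = c("correlation_grid", class(out)))
}

#' Connected components of same-sign significant tiles
#'
#' Groups significant tiles (`p < alpha`, correlation of the requested sign)
#' into connected components under 4-connectivity on the
#' (`start_pos`, `end_pos`) lattice — the stricter reading of "adjacent tiles".
#'
#' @param grid A `correlation_grid`.
#' @param sign `"negative"` or `"positive"`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble of significant tiles with a `component` id column; zero rows
#'   when nothing is significant.
#' @export
significant_components <- function(grid, sign = c("negative", "positive"),
                                   alpha = 0.05) {
  sign <- match.arg(sign)
  keep <- grid$p < alpha & if (sign == "negative") grid$r < 0 else grid$r > 0
  tiles <- grid[keep, c("series_id", "start_pos", "end_pos", "r", "p")]
  tiles$component <- NA_integer_
  if (nrow(tiles) == 0L) return(tibble::as_tibble(tiles))
  key <- paste(tiles$start_pos, tiles$end_pos)
  lookup <- setNames(seq_len(nrow(tiles)), key)
  comp <- integer(nrow(tiles))
  cur <- 0L
  for (i in seq_len(nrow(tiles))) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (comp[j] > 0L) next
      comp[j] <- cur
      nb <- c(paste(tiles$start_pos[j] - 1L, tiles$end_pos[j]),
              paste(tiles$start_pos[j] + 1L, tiles$end_pos[j]),
              paste(tiles$start_pos[j], tiles$end_pos[j] - 1L),
              paste(tiles$start_pos[j], tiles$end_pos[j] + 1L))
      hits <- lookup[nb]
      hits <- hits[!is.na(hits)]
      queue <- c(queue, hits[comp[hits] == 0L])
    }
  }
  tiles$component <- comp
  tibble::as_tibble(tiles)
}

#' Temperature-sensitivity call under the adjacency rule
#'
#' A growth series is called sensitive (per sign) when its correlation grid
#' contains a connected component of at least `min_tiles` same-sign significant
#' tiles. Requiring adjacent tiles rather than lone significant tiles acts as a
#' multiplicity control over the large pair grid.
#'
#' @param grid A `correlation_grid`.
#' @param min_tiles Minimum component size (default 3).
#' @param alpha Significance level.
#' @return Tibble (one row): `negative_sensitive`, `positive_sensitive`,
#'   `max_negative_component`, `max_positive_component`.
#' @export
call_sensitivity <- function(grid, min_tiles = 3L, alpha = 0.05) {
  sizes <- function(sign) {
    cc <- significant_components(grid, sign, alpha)
    if (nrow(cc) == 0L) 0L else max(table(cc$component))
  }
  mn <- sizes("negative"); mp <- sizes("positive")
  tibble::tibble(negative_sensitive = mn >= min_tiles,
                 positive_sensitive = mp >= min_tiles,
                 max_negative_component = as.integer(mn),
                 max_positive_component = as.integer(mp))
}

# per-tile percentage of trees significantly correlated with the given sign
tile_prevalence <- function(tree_grids, sign = c("negative", "positive"),
                            alpha = 0.05) {
  sign <- match.arg(sign)
  n_tree <- length(tree_grids)
  stopifnot(n_tree >= 1L)
  hits <- purrr::map_dfr(tree_grids, function(g) {
    sig <- g$p < alpha & if (sign == "negative") g$r < 0 else g$r > 0
    tibble::tibble(series_id = g$series_id, hit = sig)
  })
  base <- tree_grids[[1]][, c("series_id", "start_pos", "end_pos", "mean_length")]
  counts <- dplyr::summarise(dplyr::group_by(hits, .data$series_id),
                             pct = 100 * sum(.data$hit) / n_tree,
                             .groups = "drop")
  dplyr::left_join(base, counts, by = "series_id")
}

#' Maximum proportion of sensitive trees (MST)
#'
#' For every temperature series, the percentage of a population's trees whose
#' growth is significantly correlated with it (per sign); MST is the maximum of
#' these percentages over the pair grid.
#'
#' @param tree_grids List of `correlation_grid`s, one per tree, on the same
#'   batch.
#' @param sign `"negative"` or `"positive"`.
#' @param alpha Significance level.
#' @return MST in percent.
#' @export
mst <- function(tree_grids, sign = c("negative", "positive"), alpha = 0.05) {
  prev <- tile_prevalence(tree_grids, sign, alpha)
  max(prev$pct, na.rm = TRUE)
}

#' Response duration from tree-level prevalence ranking (tDur05 / tDur50)
#'
#' Ranks all temperature series in descending order of the percentage of trees
#' significantly correlated with them (ties broken by longer mean period, then
#' lower start position) and averages the mean period lengths of the top
#' `fraction` of series (count = `ceiling(fraction * N)`).
#'
#' @inheritParams mst
#' @param fraction Top fraction to average, 0.05 for tDur05 or 0.50 for tDur50.
#' @return Mean period length in days.
#' @export
tdur <- function(tree_grids, sign = c("negative", "positive"),
                 fraction = 0.05, alpha = 0.05) {
  prev <- tile_prevalence(tree_grids, sign, alpha)
  prev <- prev[order(-prev$pct, -prev$mean_length, prev$start_pos), ]
  k <- ceiling(fraction * nrow(prev))
  mean(prev$mean_length[seq_len(k)])
}

#' Response duration from population-level correlations (pDur)
#'
#' Mean of the mean period lengths of all temperature series with which the
#' population chronology is significantly correlated at the given sign.
#'
#' @param population_grid `correlation_grid` of the population chronology.
#' @inheritParams mst
#' @return Days, or `NA` when no tile qualifies.
#' @export
pdur <- function(population_grid, sign = c("negative", "positive"),
                 alpha = 0.05) {
  sign <- match.arg(sign)
  sig <- population_grid$p < alpha &
    if (sign == "negative") population_grid$r < 0 else population_grid$r > 0
  if (!any(sig)) return(NA_real_)
  mean(population_grid$mean_length[sig])
}

#' Mean coefficient of all significant correlations
#'
#' Signed mean Pearson r over every significant tile (both signs pooled) of a
#' population chronology's correlation grid.
#'
#' @inheritParams pdur
#' @return Mean r, or `NA` when no tile is significant.
#' @export
mean_significant_r <- function(population_grid, alpha = 0.05) {
  sig <- population_grid$p < alpha
  if (!any(sig)) return(NA_real_)
  mean(population_grid$r[sig])
}

#' Group a population by its sensitivity call
#'
#' Negatively-responding: any significant negative population-level response,
#' regardless of positive responses. Positively-responding: positive responses
#' only. Otherwise insensitive.
#'
#' @param call One-row tibble from [call_sensitivity()].
#' @return `"negatively_responding"`, `"positively_responding"`, or
#'   `"insensitive"`.
#' @export
group_population <- function(call) {
  if (call$negative_sensitive) "negatively_responding"
  else if (call$positive_sensitive) "positively_responding"
  else "insensitive"
}

#' Population response-structure metrics
#'
#' Convenience wrapper computing, per sign, MST, tDur05, tDur50 and pDur, plus
#' the pooled mean significant r and the population group label.
#'
#' @param tree_grids List of per-tree `correlation_grid`s.
#' @param population_grid `correlation_grid` of the population chronology.
#' @param alpha Significance level.
#' @param min_tiles Adjacency-rule component size (default 3).
#' @return Tibble with one row per sign and columns `sign`, `mst`, `tdur05`,
#'   `tdur50`, `pdur`, `mean_significant_r`, `group`.
#' @export
response_metrics <- function(tree_grids, population_grid, alpha = 0.05,
                             min_tiles = 3L) {
  call <- call_sensitivity(population_grid, min_tiles, alpha)
  grp <- group_population(call)
  mr <- mean_significant_r(population_grid, alpha)
  purrr::map_dfr(c("negative", "positive"), function(s) {
    tibble::tibble(sign = s,
                   mst = mst(tree_grids, s, alpha),
                   tdur05 = tdur(tree_grids, s, 0.05, alpha),
                   tdur50 = tdur(tree_grids, s, 0.50, alpha),
                   pdur = pdur(population_grid, s, alpha),
                   mean_significant_r = mr,
                   group = grp)
  })
}

#' Partial Pearson correlation controlling for one covariate
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p-value from a t statistic on `n - 3` degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return Tibble with `estimate`, `statistic`, `p.value`, `n`; estimate `NA`
#'   (with a warning) when a control correlation is degenerate (|r| = 1).
#' @export
partial_correlation <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  stopifnot(n >= 4L)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 1e-12) {
    warn("a control correlation is +/-1; partial correlation undefined")
    return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, n = n))
  }
  r <- (rxy - rxz * ryz) / sqrt(den)
  tstat <- r * sqrt((n - 3) / pmax(1 - r^2, .Machine$double.eps))
  tibble::tibble(estimate = r, statistic = tstat,
                 p.value = 2 * pt(abs(tstat), df = n - 3, lower.tail = FALSE),
                 n = n)
}

#' Two-sided Student's t-test between two groups
#'
#' @param a,b Numeric samples.
#' @param var_equal Pooled-variance (classical Student) test by default.
#' @return Tibble with `statistic`, `p.value`, `estimate` (mean difference),
#'   `df`.
#' @export
group_difference_test <- function(a, b, var_equal = TRUE) {
  tt <- t.test(a, b, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic),
                 p.value = tt$p.value,
                 estimate = unname(diff(rev(tt$estimate))),
                 df = unname(tt$parameter))
}
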