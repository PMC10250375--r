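years <- 1960:1990

test_that("correlation grids match the textbook Pearson computation", {
  d <- make_daily(years, function(y) sinusoid_year() + (y %% 7) * 0.3)
  b <- build_tlinked_batch(d, years)
  bm <- tlinked:::batch_matrix(b)

  # growth affine in one batch series: that tile reaches r = 1
  target <- b$pairs$series_id[50]
  g <- tibble::tibble(year = years, index = 2 + 3 * bm[, target])
  grid <- correlate(g, b)
  expect_equal(grid$r[grid$series_id == target], 1, tolerance = 1e-12)

  # r and p equal cor.test on sampled tiles
  set.seed(1)
  g2 <- tibble::tibble(year = years, index = rnorm(31))
  grid2 <- correlate(g2, b)
  for (k in sample(nrow(grid2), 10)) {
    ct <- cor.test(g2$index, bm[, grid2$series_id[k]])
    expect_equal(grid2$r[k], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(grid2$p[k], ct$p.value, tolerance = 1e-12)
  }
  expect_true(all(grid2$n == 31))
  expect_error(correlate(g2[1:10, ], b), "overlapping")
})

test_that("under the null about 5% of tiles are significant on average", {
  d <- make_daily(years, function(y) sinusoid_year() + rnorm(365, 0, 2))
  b <- build_tlinked_batch(d, years)
  set.seed(2)
  fracs <- replicate(100, {
    g <- tibble::tibble(year = years, index = rnorm(31))
    mean(correlate(g, b)$p < 0.05)
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("significant tiles group into 4-connected components", {
  # L-shape sharing edges: one component of size 3
  gL <- make_grid(c(5, 5, 6), c(10, 11, 11), r = c(-.5, -.5, -.5), p = rep(.01, 3))
  cc <- significant_components(gL, "negative")
  expect_equal(length(unique(cc$component)), 1L)
  expect_equal(nrow(cc), 3L)

  # mutually diagonal tiles: three singletons, not sensitive
  gD <- make_grid(c(5, 6, 7), c(10, 11, 12), r = rep(-.5, 3), p = rep(.01, 3))
  ccD <- significant_components(gD, "negative")
  expect_equal(length(unique(ccD$component)), 3L)
  call <- call_sensitivity(gD)
  expect_false(call$negative_sensitive)

  # random sprinklings agree with an igraph flood-fill oracle
  skip_if_not_installed("igraph")
  set.seed(3)
  for (i in 1:20) {
    n <- 60
    pos <- expand.grid(s = 1:12, e = 1:12)
    pos <- pos[pos$s < pos$e, ][sample(66, n), ]
    g <- make_grid(pos$s, pos$e, r = -abs(rnorm(n)), p = runif(n, 0, 0.2))
    cc <- significant_components(g, "negative")
    sig <- g[g$p < 0.05 & g$r < 0, ]
    if (nrow(sig) == 0) { expect_equal(nrow(cc), 0L); next }
    adj <- outer(seq_len(nrow(sig)), seq_len(nrow(sig)), function(i, j) {
      abs(sig$start_pos[i] - sig$start_pos[j]) +
        abs(sig$end_pos[i] - sig$end_pos[j]) == 1
    })
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    oracle <- igraph::components(gr)$membership
    expect_equal(nrow(cc), nrow(sig))
    # same partition (component labels may differ)
    key <- paste(cc$start_pos, cc$end_pos)
    okey <- paste(sig$start_pos, sig$end_pos)
    cmap <- cc$component[match(okey, key)]
    expect_equal(length(unique(paste(cmap, oracle))),
                 length(unique(cmap)))
    expect_equal(length(unique(cmap)), length(unique(oracle)))
  }
})

test_that("sensitivity calls require a component of three tiles per sign", {
  empty <- make_grid(integer(), integer(), r = numeric(), p = numeric())
  call0 <- call_sensitivity(empty)
  expect_false(call0$negative_sensitive || call0$positive_sensitive)

  g5 <- make_grid(1:5, rep(8, 5), r = rep(-.6, 5), p = rep(.001, 5))
  expect_true(call_sensitivity(g5)$negative_sensitive)
  expect_false(call_sensitivity(g5)$positive_sensitive)

  # both signs can be flagged simultaneously
  gb <- make_grid(c(1:3, 6:8), rep(9, 6), r = c(rep(-.6, 3), rep(.6, 3)),
                  p = rep(.001, 6))
  cb <- call_sensitivity(gb)
  expect_true(cb$negative_sensitive && cb$positive_sensitive)
})

test_that("the adjacency rule is a multiplicity control for independent tiles", {
  # small grid (H = 2 geometry, 36 tiles), iid p-values
  pos <- which(upper.tri(matrix(0, 9, 9)), arr.ind = TRUE)
  set.seed(4)
  res <- t(replicate(400, {
    g <- make_grid(pos[, 1], pos[, 2], r = rnorm(36, 0, 0.3), p = runif(36))
    cs <- call_sensitivity(g)
    c(cluster = cs$negative_sensitive || cs$positive_sensitive,
      any_tile = any(g$p < 0.05))
  }))
  expect_lt(mean(res[, "cluster"]), 0.05)
  expect_lte(mean(res[, "cluster"]), mean(res[, "any_tile"]))
})

test_that("MST is the maximum per-tile prevalence across trees", {
  # 10 trees; one tile significant for 4 of them
  grids <- lapply(1:10, function(tr) {
    make_grid(c(2, 3), c(5, 6), r = c(-.5, -.5),
              p = c(if (tr <= 4) 0.01 else 0.5, 0.5))
  })
  expect_equal(mst(grids, "negative"), 40)
  expect_equal(mst(grids, "positive"), 0)

  prev <- tlinked:::tile_prevalence(grids, "negative")
  expect_true(all(mst(grids, "negative") >= prev$pct))
})

test_that("tDur ranks tiles by prevalence with deterministic tie-breaking", {
  # 20 tiles, one dominant: top 5% (ceil -> 1 tile) is that tile's length
  set.seed(5)
  lens <- seq(10, 105, by = 5)
  grids <- lapply(1:5, function(tr) {
    make_grid(1:20, rep(25, 20), r = rep(-.5, 20),
              p = c(0.01, rep(0.9, 19)), mean_length = lens)
  })
  expect_equal(tdur(grids, "negative", 0.05), lens[1])
  # top 50%: the dominant tile plus the 9 longest ties
  expect_equal(tdur(grids, "negative", 0.50),
               mean(c(lens[1], sort(lens[-1], decreasing = TRUE)[1:9])))

  # all tied at 0%: average of top ceil(f*N) under the tie rule
  grids0 <- lapply(1:3, function(tr) {
    make_grid(1:20, rep(25, 20), r = rep(.1, 20), p = rep(.9, 20),
              mean_length = lens)
  })
  expect_equal(tdur(grids0, "negative", 0.05), max(lens))

  # sort-then-average oracle on random prevalence fixtures
  for (i in 1:10) {
    ps <- sample(c(0.01, 0.5), 20, replace = TRUE)
    grids_r <- lapply(1:4, function(tr) {
      make_grid(1:20, rep(25, 20), r = rep(-.4, 20),
                p = sample(ps), mean_length = lens)
    })
    prev <- tlinked:::tile_prevalence(grids_r, "negative")
    ord <- order(-prev$pct, -prev$mean_length, prev$start_pos)
    k <- ceiling(0.5 * 20)
    expect_equal(tdur(grids_r, "negative", 0.5),
                 mean(prev$mean_length[ord][1:k]))
  }
})

test_that("pDur and mean significant r summarize population-level tiles", {
  g <- make_grid(c(1, 2, 4), c(8, 9, 9), r = c(-.5, -.4, .45),
                 p = c(.01, .02, .03), mean_length = c(30, 50, 70))
  expect_equal(pdur(g, "negative"), 40)
  expect_equal(pdur(g, "positive"), 70)
  expect_equal(mean_significant_r(g), mean(c(-.5, -.4, .45)))

  g2 <- make_grid(1, 8, r = .2, p = .5)
  expect_true(is.na(pdur(g2, "negative")))
  expect_true(is.na(mean_significant_r(g2)))

  g3 <- make_grid(c(1, 2), c(8, 8), r = c(.5, -.5), p = c(.01, .01))
  expect_equal(mean_significant_r(g3), 0)
})

test_that("population grouping follows the negative-priority rule", {
  mk <- function(neg, pos) tibble::tibble(negative_sensitive = neg,
                                          positive_sensitive = pos)
  expect_equal(group_population(mk(TRUE, TRUE)), "negatively_responding")
  expect_equal(group_population(mk(TRUE, FALSE)), "negatively_responding")
  expect_equal(group_population(mk(FALSE, TRUE)), "positively_responding")
  expect_equal(group_population(mk(FALSE, FALSE)), "insensitive")
})

test_that("partial correlation matches its closed form and limits", {
  set.seed(6)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200); z <- rnorm(200)
  pc <- partial_correlation(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$estimate, oracle, tolerance = 1e-12)
  t_or <- oracle * sqrt(197 / (1 - oracle^2))
  expect_equal(pc$p.value, 2 * pt(abs(t_or), 197, lower.tail = FALSE),
               tolerance = 1e-12)

  # independent control leaves the correlation essentially unchanged
  expect_equal(pc$estimate, rxy, tolerance = 0.1)

  # y == z: degenerate, flagged
  expect_warning(pc2 <- partial_correlation(x, y, y), "undefined")
  expect_true(is.na(pc2$estimate))
})

test_that("group difference test is a two-sided Student's t", {
  a <- c(1, 2, 3, 4, 5)
  same <- group_difference_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(7)
  ps <- replicate(100, group_difference_test(rnorm(100), rnorm(100, 1))$p.value)
  expect_gte(mean(ps < 0.001), 0.95)

  b <- c(2, 4, 5, 7, 9)
  tt <- t.test(a, b, var.equal = TRUE)
  out <- group_difference_test(a, b)
  expect_equal(out$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p.value, tt$p.value, tolerance = 1e-12)
  expect_equal(out$estimate, mean(a) - mean(b))
})
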