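# reference coefficients (plus-exponent convention)
SIB <- c(w1 = -0.5974, w2 = 0.01212, w3 = -7.3368)
DAH <- c(w1 = -0.7363, w2 = 0.01737, w3 = -14.0796)

test_that("fitting recovers the generating model and its sign convention", {
  obs <- gen_logistic_observations(SIB[1], SIB[2], SIB[3], n = 2000, seed = 10)
  m <- fit_logistic(obs, species = "siberian_larch")
  expect_equal(climate_boundary(m)$slope, 49.29, tolerance = 0.1)
  expect_gt(m$pseudo_r2, 0.1)
  expect_true(all(m$wald_p[c("w1", "w2")] < 0.001))

  # the plus-exponent trap: w must be the NEGATIVE of the glm coefficients
  y <- obs$group == "negative"
  gfit <- glm(y ~ MAT + MAP, family = binomial(), data = obs)
  expect_equal(unname(m$w), unname(-coef(gfit)[c("MAT", "MAP", "(Intercept)")]),
               tolerance = 1e-9)
  # and probability() must reproduce glm's fitted values
  expect_equal(probability(m, obs$MAT, obs$MAP), unname(fitted(gfit)),
               tolerance = 1e-9)

  # group-independent labels give a null pseudo-R2
  obs0 <- obs
  withr::with_seed(11, obs0$group <- sample(obs0$group))
  m0 <- fit_logistic(obs0)
  expect_lt(m0$pseudo_r2, 0.02)

  expect_error(fit_logistic(dplyr::mutate(obs, group = "negative")), "both")

  # perfect separation is detected and the direction reported
  sep <- tibble::tibble(MAT = c(rnorm(30, -10), rnorm(30, 0)),
                        MAP = rnorm(60, 500, 10),
                        group = rep(c("positive", "negative"), each = 30))
  expect_error(fit_logistic(sep), "separation")
})

test_that("tidy and glance expose the model in the written convention", {
  obs <- gen_logistic_observations(SIB[1], SIB[2], SIB[3], n = 500, seed = 12)
  m <- fit_logistic(obs)
  td <- tidy(m)
  expect_equal(td$term, c("MAT", "MAP", "(Intercept)"))
  expect_equal(td$estimate, unname(m$w))
  gl <- glance(m)
  expect_equal(gl$pseudo_r2, 1 - m$loglik / m$loglik_null)
  expect_equal(gl$n, 500L)
})

test_that("probability follows the logistic form with its limits", {
  m <- larch_reference_models()$siberian_larch
  # at MAT = 0 the P0 = 0.5 boundary sits at MAP = -w3/w2 = 605.3 mm
  expect_equal(probability(m, 0, 605.3), 0.5, tolerance = 1e-3)
  expect_equal(probability(m, 1e4, 0), 1)   # exponent -> -Inf
  expect_equal(probability(m, -1e4, 0), 0)  # exponent -> +Inf

  # w1 < 0: warming at fixed precipitation raises the negative-response odds
  md <- larch_reference_models()$dahurian_larch
  p <- probability(md, seq(-15, 5, 1), 400)
  expect_true(all(diff(p) > 0))
})

test_that("climate boundaries have the published slopes, independent of P0", {
  ms <- larch_reference_models()
  bs <- climate_boundary(ms$siberian_larch, c(0.5, 0.75, 0.95))
  bd <- climate_boundary(ms$dahurian_larch, c(0.5, 0.75, 0.95))
  expect_equal(round(unique(bs$slope), 1), 49.3)
  expect_equal(round(unique(bd$slope), 1), 42.4)
  expect_equal(length(unique(bs$slope)), 1L)
  # intercepts satisfy the boundary identity w1*0 + w2*MAP + w3 = ln(1/P0 - 1)
  expect_equal(bs$intercept[1], (log(1) - (-7.3368)) / 0.01212, tolerance = 1e-9)
})

test_that("cross-validation scores classification accuracy and kappa", {
  # perfectly separable (wide margin) data
  sep <- tibble::tibble(MAT = c(rnorm(100, -12, 1), rnorm(100, 2, 1)),
                        MAP = rep(500, 200),
                        group = rep(c("positive", "negative"), each = 100))
  cv <- cross_validate(sep, k = 10, seed = 3)
  expect_equal(mean(cv$accuracy), 1)
  expect_equal(mean(cv$kappa), 1)

  # shuffled labels: chance-level kappa
  obs <- gen_logistic_observations(SIB[1], SIB[2], SIB[3], n = 2000, seed = 14)
  withr::with_seed(15, obs$group <- sample(obs$group))
  cv0 <- cross_validate(obs, k = 10, seed = 3)
  expect_lt(abs(mean(cv0$kappa)), 0.1)

  # kappa equals the contingency-table oracle
  set.seed(16)
  for (i in 1:20) {
    pred <- runif(50) > 0.5; o <- runif(50) > 0.4
    po <- mean(pred == o)
    pe <- mean(pred) * mean(o) + (1 - mean(pred)) * (1 - mean(o))
    expect_equal(tlinked:::cohens_kappa(pred, o), (po - pe) / (1 - pe),
                 tolerance = 1e-12)
  }

  # realistic data: summary attribute carries means and SDs
  cvr <- cross_validate(gen_logistic_observations(SIB[1], SIB[2], SIB[3],
                                                  n = 300, seed = 17),
                        k = 10, seed = 4)
  sm <- attr(cvr, "summary")
  expect_equal(sm$accuracy_mean, mean(cvr$accuracy))
  expect_gt(sm$accuracy_mean, 0.7)
})

test_that("grid classification splits climate space along the boundary", {
  m <- larch_reference_models()$siberian_larch
  nr <- 60; nc <- 60
  mat <- climate_grid(matrix(seq(-15, 5, length.out = nc), nr, nc, byrow = TRUE),
                      variable = "MAT")
  map <- climate_grid(matrix(seq(900, 150, length.out = nr), nr, nc),
                      variable = "MAP")

  rm50 <- classify_grid(m, mat, map, P0 = 0.5)
  b <- climate_boundary(m, 0.5)
  # geometric oracle: negative iff MAP < slope*MAT + intercept
  oracle <- map$values < b$slope * mat$values + b$intercept
  mismatch <- sum((rm50$labels == "negative") != oracle)
  expect_lte(mismatch, nc)  # at most one cell per column along the line

  # all-positive grid
  warm <- climate_grid(matrix(900, 10, 10), variable = "MAP")
  cold <- climate_grid(matrix(-15, 10, 10), variable = "MAT")
  rm0 <- classify_grid(m, cold, warm, P0 = 0.5)
  expect_equal(rm0$areas$percent[rm0$areas$label == "negative"], 0)

  # latitude weighting shrinks the share of high-latitude cells: put the
  # negative (dry-warm) cells in the northern rows of a 50-70 degN grid
  mat_n <- climate_grid(matrix(c(rep(5, 30 * 60), rep(-15, 30 * 60)), 60, 60,
                               byrow = TRUE), yll = 50, cellsize = 1/3,
                        variable = "MAT")
  map_n <- climate_grid(matrix(300, 60, 60), yll = 50, cellsize = 1/3,
                        variable = "MAP")
  raw <- classify_grid(m, mat_n, map_n, P0 = 0.5)
  wgt <- classify_grid(m, mat_n, map_n, P0 = 0.5, latitude_weighted = TRUE)
  pct <- function(x) x$areas$percent[x$areas$label == "negative"]
  expect_equal(pct(raw), 50)
  expect_lt(pct(wgt), 50)

  # monotone nesting of thresholds
  neg <- function(p0) classify_grid(m, mat, map, P0 = p0)$labels == "negative"
  n50 <- neg(0.5); n75 <- neg(0.75); n95 <- neg(0.95)
  expect_true(all(n95 <= n75))
  expect_true(all(n75 <= n50))
})

test_that("ensemble projections count agreeing GCMs per cell", {
  m <- larch_reference_models()$siberian_larch
  base_mat <- matrix(seq(-10, 2, length.out = 20), 20, 20, byrow = TRUE)
  base_map <- matrix(500, 20, 20)
  mk <- function(dt) list(mat = climate_grid(base_mat + dt, variable = "MAT"),
                          map = climate_grid(base_map, variable = "MAP"))

  # all models identical: counts are 0 or n everywhere
  same <- replicate(5, mk(0), simplify = FALSE)
  ep <- ensemble_projection(m, same, P0 = 0.5)
  expect_true(all(ep$agreement_count %in% c(0L, 5L)))

  # 18 of 25 agreeing: negative under the explicit n >= 18 convention,
  # positive under the default ceiling(0.75 * 25) = 19
  gcms <- c(replicate(18, mk(10), simplify = FALSE),
            replicate(7, mk(-30), simplify = FALSE))
  cell <- which(base_mat == max(base_mat), arr.ind = TRUE)[1, ]
  ep18 <- ensemble_projection(m, gcms, P0 = 0.5, min_models = 18)
  ep19 <- ensemble_projection(m, gcms, P0 = 0.5, agreement = 0.75)
  expect_equal(ep18$agreement_count[cell[1], cell[2]], 18)
  expect_equal(ep18$labels[cell[1], cell[2]], "negative")
  expect_equal(ep19$min_models, 19)
  expect_equal(ep19$labels[cell[1], cell[2]], "positive")

  # counts equal per-model reclassification
  counts <- Reduce(`+`, lapply(gcms, function(g) {
    classify_grid(m, g$mat, g$map, P0 = 0.5)$labels == "negative"
  }))
  expect_equal(ep18$agreement_count, counts)
})

test_that("projected cells outside the baseline climate hull are flagged", {
  set.seed(18)
  bm <- climate_grid(matrix(runif(400, -12, 0), 20, 20), variable = "MAT")
  bp <- climate_grid(matrix(runif(400, 300, 700), 20, 20), variable = "MAP")

  # projection identical to baseline: nothing outside
  out0 <- climate_space_mask(bm, bp, bm, bp)
  expect_false(any(out0))

  # hotter than the baseline maximum everywhere: everything outside
  hot <- climate_grid(matrix(max(bm$values) + 10, 20, 20), variable = "MAT")
  expect_true(all(climate_space_mask(bm, bp, hot, bp)))

  # hull membership matches a ray-casting oracle
  pm <- climate_grid(matrix(runif(400, -14, 2), 20, 20), variable = "MAT")
  pp <- climate_grid(matrix(runif(400, 250, 750), 20, 20), variable = "MAP")
  out <- climate_space_mask(bm, bp, pm, pp)
  base <- cbind(as.vector(bm$values), as.vector(bp$values))
  h <- grDevices::chull(base); poly <- base[c(h, h[1]), ]
  oracle <- !mapply(function(x, y) pip_oracle(poly, x, y),
                    as.vector(pm$values), as.vector(pp$values))
  expect_gte(mean(as.vector(out) == oracle), 0.999)

  # box envelope is looser than the hull
  out_box <- climate_space_mask(bm, bp, pm, pp, envelope = "box")
  expect_true(all(out >= out_box))
})
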