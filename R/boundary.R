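#' Logistic climate-boundary model of negative temperature response
#'
#' The probability that a population responds negatively to temperature is
#' modelled as `P = 1 / (1 + exp(w1*MAT + w2*MAP + w3))`. Note the exponent
#' carries a plus sign, so `(w1, w2, w3)` are the negatives of the conventional
#' logit coefficients; `fit_logistic()` fits the conventional GLM and negates.
#'
#' @param w1 MAT coefficient (per degC).
#' @param w2 MAP coefficient (per mm).
#' @param w3 Intercept (dimensionless).
#' @param species Optional species tag.
#' @return A `boundary_model` object.
#' @export
boundary_model <- function(w1, w2, w3, species = NA_character_) {
  structure(list(w = c(w1 = w1, w2 = w2, w3 = w3), species = species,
                 se = NULL, wald_p = NULL, loglik = NA_real_,
                 loglik_null = NA_real_, pseudo_r2 = NA_real_, n = NA_integer_,
                 fit = NULL),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("<boundary_model%s: P = 1/(1 + exp(%.4g*MAT + %.4g*MAP + %.4g))%s>\n",
              if (is.na(x$species)) "" else paste0(" ", x$species),
              x$w[1], x$w[2], x$w[3],
              if (is.na(x$pseudo_r2)) "" else
                sprintf(", pseudo-R2 = %.3f, n = %d", x$pseudo_r2, x$n)))
  invisible(x)
}

#' Fit the logistic climate-boundary model
#'
#' Maximum-likelihood logistic regression of the binary response group on MAT
#' and MAP, reported in the plus-exponent convention of [boundary_model()].
#' McFadden's pseudo-R2 is `1 - logLik(model)/logLik(null)`; Wald z-tests per
#' coefficient.
#'
#' @param observations Data frame with columns `MAT` (degC), `MAP` (mm) and
#'   `group` (`"negative"`/`"positive"`, logical, or 0/1 with 1 = negative
#'   response).
#' @param species Optional species tag.
#' @param allow_separation Do not error on perfectly separated groups (used
#'   internally by [cross_validate()], where prediction is still well defined).
#' @return A fitted `boundary_model`.
#' @export
fit_logistic <- function(observations, species = NA_character_,
                         allow_separation = FALSE) {
  y <- observations$group
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "negative"
  y <- as.integer(y)
  stopifnot(length(y) >= 20L)
  if (length(unique(y)) < 2L) abort("both response groups must be present")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ MAT + MAP, family = binomial(), data = observations,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!allow_separation && sep_warn &&
      all((fitted(fit) >= 0.5) == y) &&
      (max(fitted(fit)) > 1 - 1e-6 || min(fitted(fit)) < 1e-6)) {
    dir <- coef(fit)[-1]
    abort(sprintf(
      "perfect separation: groups are split along the direction (MAT: %s, MAP: %s)",
      ifelse(dir[1] > 0, "+", "-"), ifelse(dir[2] > 0, "+", "-")))
  }
  cf <- coef(fit)
  cf[is.na(cf)] <- 0  # aliased predictor (e.g. constant column)
  sm <- summary(fit)$coefficients
  pick <- function(term, col) if (term %in% rownames(sm)) sm[term, col] else NA_real_
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  m <- boundary_model(w1 = -cf[["MAT"]], w2 = -cf[["MAP"]],
                      w3 = -cf[["(Intercept)"]], species = species)
  m$se <- c(w1 = pick("MAT", 2), w2 = pick("MAP", 2), w3 = pick("(Intercept)", 2))
  m$wald_p <- c(w1 = pick("MAT", 4), w2 = pick("MAP", 4),
                w3 = pick("(Intercept)", 4))
  m$loglik <- ll
  m$loglik_null <- ll0
  m$pseudo_r2 <- 1 - ll / ll0
  m$n <- length(y)
  m$fit <- fit
  m
}

#' @export
tidy.boundary_model <- function(x, ...) {
  tibble::tibble(term = c("MAT", "MAP", "(Intercept)"),
                 estimate = unname(x$w),
                 std.error = if (is.null(x$se)) NA_real_ else unname(x$se),
                 p.value = if (is.null(x$wald_p)) NA_real_ else unname(x$wald_p))
}

#' @export
glance.boundary_model <- function(x, ...) {
  tibble::tibble(pseudo_r2 = x$pseudo_r2, logLik = x$loglik,
                 logLik_null = x$loglik_null, n = x$n, species = x$species)
}

#' Probability of negative response at given climate coordinates
#'
#' @param model A `boundary_model`.
#' @param MAT,MAP Numeric vectors (degC, mm), recycled.
#' @return Probabilities in (0, 1).
#' @export
probability <- function(model, MAT, MAP) {
  w <- unname(model$w)
  1 / (1 + exp(w[1] * MAT + w[2] * MAP + w[3]))
}

#' Climate boundary line at a probability threshold
#'
#' Solves `w1*MAT + w2*MAP + w3 = ln(1/P0 - 1)` for the line in (MAT, MAP)
#' space separating negatively- from positively-responding climates. The slope
#' `-w1/w2` (mm per degC) is independent of the threshold.
#'
#' @param model A `boundary_model`.
#' @param P0 Probability threshold(s).
#' @return Tibble with `P0`, `slope` (mm per degC), `intercept` (MAP at
#'   MAT = 0, mm).
#' @export
climate_boundary <- function(model, P0 = 0.5) {
  stopifnot(all(P0 > 0 & P0 < 1))
  tibble::tibble(P0 = P0,
                 slope = -model$w[[1]] / model$w[[2]],
                 intercept = (log(1 / P0 - 1) - model$w[[3]]) / model$w[[2]])
}

# Cohen's kappa from predicted/observed binary labels
cohens_kappa <- function(pred, obs) {
  po <- mean(pred == obs)
  pe <- mean(pred) * mean(obs) + mean(!pred) * mean(!obs)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' K-fold cross-validation of the boundary model
#'
#' Random partition into `k` folds of near-equal size; each fold is predicted
#' from a model fit on the others, classifying negative where the predicted
#' probability is at least 0.5. If any training split lacks one of the classes
#' the folds are re-randomized (at most `max_attempts` times).
#'
#' @param observations As in [fit_logistic()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param max_attempts Re-randomizations allowed for degenerate folds.
#' @return Tibble with per-fold `fold`, `accuracy`, `kappa`; summary means and
#'   SDs in attributes `summary`.
#' @export
cross_validate <- function(observations, k = 10L, seed = 1L, max_attempts = 10L) {
  y <- observations$group
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "negative"
  y <- as.logical(as.integer(y))
  n <- length(y)
  folds <- NULL
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      f <- sample(rep(seq_len(k), length.out = n))
      ok <- all(vapply(seq_len(k), function(i) length(unique(y[f != i])) == 2L,
                       logical(1)))
      if (ok) { folds <- f; break }
    }
  })
  if (is.null(folds)) abort("could not build folds with both classes in every training split")
  res <- purrr::map_dfr(seq_len(k), function(i) {
    train <- observations[folds != i, , drop = FALSE]
    test <- observations[folds == i, , drop = FALSE]
    m <- fit_logistic(train, allow_separation = TRUE)
    pred <- probability(m, test$MAT, test$MAP) >= 0.5
    obs <- y[folds == i]
    tibble::tibble(fold = i, accuracy = mean(pred == obs),
                   kappa = cohens_kappa(pred, obs))
  })
  structure(res, summary = tibble::tibble(
    accuracy_mean = mean(res$accuracy), accuracy_sd = sd(res$accuracy),
    kappa_mean = mean(res$kappa), kappa_sd = sd(res$kappa)))
}

#' Classify a climate raster into response regions
#'
#' Evaluates the negative-response probability on paired MAT/MAP grids and
#' labels each in-habitat cell `negative` where `P >= P0`, else `positive`.
#' Cells flagged outside the baseline climate space become
#' `outside_climate_space`; cells outside the species mask are `non_habitat`.
#'
#' @param model A `boundary_model`.
#' @param mat,map [climate_grid] objects (aligned).
#' @param mask Logical matrix (species distribution), or `NULL` for all cells.
#' @param P0 Probability threshold.
#' @param outside Optional logical matrix marking cells outside the baseline
#'   climate space (see [climate_space_mask()]).
#' @param latitude_weighted Weight area percentages by the cosine of each
#'   cell-row's latitude (true cell area) instead of raw cell counts.
#' @return A `response_region_map`: list with `probability` (matrix), `labels`
#'   (character matrix), `P0`, area summary tibble `areas` (percent of habitat
#'   area per label), and the grids' labels.
#' @export
classify_grid <- function(model, mat, map, mask = NULL, P0 = 0.5,
                          outside = NULL, latitude_weighted = FALSE) {
  check_grid_pair(mat, map)
  if (is.null(mask)) mask <- !is.na(mat$values) & !is.na(map$values)
  p <- matrix(probability(model, as.vector(mat$values), as.vector(map$values)),
              nrow(mat$values), ncol(mat$values))
  labels <- matrix("non_habitat", nrow(p), ncol(p))
  inh <- mask & !is.na(p)
  labels[inh & p >= P0] <- "negative"
  labels[inh & p < P0] <- "positive"
  if (!is.null(outside)) labels[inh & outside] <- "outside_climate_space"
  w <- matrix(1, nrow(p), ncol(p))
  if (latitude_weighted) {
    # row 1 is the northernmost row; latitude at each row centre
    lat <- mat$yll + (nrow(p) - seq_len(nrow(p)) + 0.5) * mat$cellsize
    w[] <- rep(cos(pmin(pmax(lat, -89.9), 89.9) * pi / 180), ncol(p))
  }
  tot <- sum(w[inh])
  areas <- tibble::tibble(
    label = c("negative", "positive", "outside_climate_space"),
    percent = 100 * c(sum(w[labels == "negative"]), sum(w[labels == "positive"]),
                      sum(w[labels == "outside_climate_space"])) / max(tot, 1e-12))
  structure(list(probability = p, labels = labels, P0 = P0, areas = areas,
                 period_label = mat$period_label,
                 scenario_label = mat$scenario_label,
                 model_label = mat$model_label),
            class = "response_region_map")
}

#' @export
print.response_region_map <- function(x, ...) {
  cat(sprintf("<response_region_map P0 = %.2f>\n", x$P0))
  print(x$areas)
  invisible(x)
}

#' Ensemble classification over GCM projections
#'
#' Counts, per grid cell, how many GCMs project a negative-response climate
#' (`P >= P0`) and labels a cell negative where the count reaches the agreement
#' threshold — `ceiling(agreement * n_models)` by default, or an explicit
#' `min_models` count.
#'
#' @param model A `boundary_model`.
#' @param gcm_grids List of GCM projections, each `list(mat =, map =)` of
#'   aligned [climate_grid]s.
#' @param mask Logical habitat matrix or `NULL`.
#' @param P0 Probability threshold.
#' @param agreement Required agreeing fraction of GCMs (default 0.75).
#' @param min_models Explicit minimum count overriding `agreement` (e.g. 18 of
#'   25 models).
#' @param outside Optional outside-climate-space matrix.
#' @return A `response_region_map` with an extra `agreement_count` matrix and
#'   `n_models`.
#' @export
ensemble_projection <- function(model, gcm_grids, mask = NULL, P0 = 0.5,
                                agreement = 0.75, min_models = NULL,
                                outside = NULL) {
  stopifnot(length(gcm_grids) >= 1L)
  maps <- purrr::map(gcm_grids, function(g) {
    classify_grid(model, g$mat, g$map, mask = mask, P0 = P0)
  })
  counts <- Reduce(`+`, purrr::map(maps, function(m) m$labels == "negative"))
  n_models <- length(gcm_grids)
  need <- min_models %||% ceiling(agreement * n_models)
  ref <- maps[[1]]
  labels <- ref$labels
  inh <- labels != "non_habitat"
  labels[inh] <- ifelse(counts[inh] >= need, "negative", "positive")
  if (!is.null(outside)) labels[inh & outside] <- "outside_climate_space"
  n_hab <- sum(inh)
  areas <- tibble::tibble(
    label = c("negative", "positive", "outside_climate_space"),
    percent = 100 * c(sum(labels == "negative"), sum(labels == "positive"),
                      sum(labels == "outside_climate_space")) / max(n_hab, 1L))
  structure(list(probability = NULL, labels = labels, agreement_count = counts,
                 n_models = n_models, min_models = need, P0 = P0, areas = areas,
                 period_label = gcm_grids[[1]]$mat$period_label,
                 scenario_label = gcm_grids[[1]]$mat$scenario_label,
                 model_label = NA_character_),
            class = "response_region_map")
}

#' Flag projected cells outside the baseline climate space
#'
#' A projected cell is outside when its (MAT, MAP) pair falls outside the
#' convex hull of the baseline (MAT, MAP) values over the species mask — the
#' tightest convex envelope of the climates the boundary model was fitted
#' within. An axis-aligned bounding-box envelope is available as a looser
#' alternative.
#'
#' @param baseline_mat,baseline_map Baseline [climate_grid]s.
#' @param projected_mat,projected_map Projected [climate_grid]s.
#' @param mask Logical habitat matrix or `NULL`.
#' @param envelope `"hull"` (convex hull) or `"box"`.
#' @return Logical matrix, `TRUE` where the projected climate is outside the
#'   baseline climate space.
#' @export
climate_space_mask <- function(baseline_mat, baseline_map, projected_mat,
                               projected_map, mask = NULL,
                               envelope = c("hull", "box")) {
  envelope <- match.arg(envelope)
  check_grid_pair(baseline_mat, baseline_map)
  check_grid_pair(projected_mat, projected_map)
  if (is.null(mask)) {
    mask <- !is.na(baseline_mat$values) & !is.na(baseline_map$values)
  }
  base <- cbind(as.vector(baseline_mat$values)[mask],
                as.vector(baseline_map$values)[mask])
  base <- base[stats::complete.cases(base), , drop = FALSE]
  pts <- cbind(as.vector(projected_mat$values), as.vector(projected_map$values))
  out <- rep(NA, nrow(pts))
  ok <- stats::complete.cases(pts)
  if (envelope == "box") {
    rngT <- range(base[, 1]); rngP <- range(base[, 2])
    inside <- pts[ok, 1] >= rngT[1] & pts[ok, 1] <= rngT[2] &
      pts[ok, 2] >= rngP[1] & pts[ok, 2] <= rngP[2]
  } else {
    h <- grDevices::chull(base)
    poly <- base[c(h, h[1]), , drop = FALSE]
    inside <- mgcv::in.out(poly, pts[ok, , drop = FALSE])
    # in.out excludes boundary points; accept them via a tiny hull inflation
    if (!all(inside)) {
      ctr <- colMeans(base)
      poly2 <- sweep(sweep(poly, 2, ctr), 2, c(1, 1) * (1 + 1e-9), `*`)
      poly2 <- sweep(poly2, 2, ctr, `+`)
      inside <- inside | mgcv::in.out(poly2, pts[ok, , drop = FALSE])
    }
  }
  out[ok] <- !inside
  matrix(out, nrow(projected_mat$values), ncol(projected_mat$values))
}
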