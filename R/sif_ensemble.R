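# SIF-proxy model weighting: per-biome GPP-SIF correlations (spatial or
# temporal mode), area-weighted model scores, order-gamma weights, the
# weighted ensemble, and the leave-one-out stability comparison against
# unweighted averaging.

#' Per-biome correlation of one model's GPP with SIF
#'
#' In `spatial` mode both fields are averaged over the training years to
#' one annual map each, and for each biome the fraction-weighted Pearson
#' correlation is taken across land cells (cell weight = area x biome
#' fraction). In `temporal` mode each field is averaged spatially within
#' the biome for every training month (fraction-and-area weighted) and
#' the two monthly series are correlated.
#'
#' Monthly GPP input is aggregated with annual sums, SIF with annual
#' means, before spatial-mode averaging. Biomes with fewer than 3
#' effective samples get an `NA` entry, flagged for exclusion (and area
#' renormalisation) during scoring.
#'
#' @param model_gpp GPP [gridded_cube()] (monthly or annual).
#' @param sif SIF cube on the same grid (monthly or annual).
#' @param biomes A [biome_fractions()].
#' @param mode `"spatial"` or `"temporal"`.
#' @param training_years Years used for the correlation (e.g. 2007:2011).
#' @param weights Optional [area_weights()].
#' @param membership `"fractional"` (default: each cell contributes to
#'   every biome in proportion to its fraction) or `"dominant"`.
#' @return Named numeric vector of correlations per biome, with attribute
#'   `n_eff` (effective sample counts).
#' @export
biome_correlations <- function(model_gpp, sif, biomes,
                               mode = c("spatial", "temporal"),
                               training_years, weights = NULL,
                               membership = c("fractional", "dominant")) {
  mode <- match.arg(mode)
  membership <- match.arg(membership)
  if (!grids_equal(model_gpp$grid, sif$grid) ||
      !grids_equal(model_gpp$grid, biomes$grid)) {
    validation_error("model GPP, SIF and biomes must share a grid")
  }
  if (is.null(weights)) weights <- area_weights(model_gpp$grid)
  common <- intersect(intersect(cube_years(model_gpp), cube_years(sif)),
                      training_years)
  if (length(common) == 0) {
    validation_error("no overlap between cubes and training years")
  }
  J <- length(biomes$labels)
  frac <- biomes$fractions
  if (membership == "dominant") {
    dom <- apply(frac, c(2, 3), which.max)
    frac <- array(0, dim(frac))
    for (j in seq_len(J)) frac[j, , ] <- (dom == j) + 0
  }
  mask <- model_gpp$mask & sif$mask
  r <- stats::setNames(rep(NA_real_, J), biomes$labels)
  n_eff <- stats::setNames(integer(J), biomes$labels)

  if (mode == "spatial") {
    gpp_ann <- if (model_gpp$freq == "monthly") {
      to_annual(model_gpp, "sum")
    } else model_gpp
    sif_ann <- if (sif$freq == "monthly") to_annual(sif, "mean") else sif
    gmap <- cube_time_mean(select_years(gpp_ann, common))
    smap <- cube_time_mean(select_years(sif_ann, common))
    for (j in seq_len(J)) {
      w <- weights$values * frac[j, , ]
      w[!mask] <- 0
      n_eff[j] <- sum(w > 0)
      if (n_eff[j] >= 3) {
        r[j] <- weighted_pearson(as.vector(gmap$values), as.vector(smap$values),
                                 as.vector(w))
      }
    }
  } else {
    if (model_gpp$freq != "monthly" || sif$freq != "monthly") {
      validation_error("temporal mode requires monthly cubes")
    }
    gpp_t <- select_years(model_gpp, common)
    sif_t <- select_years(sif, common)
    nt <- length(gpp_t$time)
    G <- matrix(gpp_t$values, nt, prod(dim(gpp_t$values)[2:3]))
    S <- matrix(sif_t$values, nt, ncol(G))
    for (j in seq_len(J)) {
      w <- as.vector(weights$values * frac[j, , ])
      w[!as.vector(mask)] <- 0
      idx <- which(w > 0)
      n_eff[j] <- length(idx)
      if (length(idx) >= 1) {
        gw <- as.vector(G[, idx, drop = FALSE] %*% w[idx]) / sum(w[idx])
        sw <- as.vector(S[, idx, drop = FALSE] %*% w[idx]) / sum(w[idx])
        if (nt >= 3) r[j] <- stats::cor(gw, sw)
      }
      if (nt < 3) n_eff[j] <- 0L
    }
  }
  attr(r, "n_eff") <- n_eff
  attr(r, "mode") <- mode
  r
}

#' Overall score of a model
#'
#' Area-weighted average of the per-biome correlations,
#' `score_i = sum_j a_j r_ij`, with the area fractions renormalised over
#' the biomes whose correlation is defined.
#'
#' @param corr_row Named correlations from [biome_correlations()].
#' @param a Biome area fractions (non-negative, summing to 1), aligned
#'   with `corr_row`.
#' @return Scalar score.
#' @export
model_score <- function(corr_row, a) {
  if (length(corr_row) != length(a)) {
    validation_error("area fractions must align with the biome axis")
  }
  if (any(a < 0)) validation_error("area fractions must be non-negative")
  ok <- !is.na(corr_row)
  if (!any(ok)) gppiav_error("gppiav_validation_error",
                             "all biome correlations undefined")
  a_ok <- a[ok] / sum(a[ok])
  sum(a_ok * corr_row[ok])
}

#' Biome area fractions over the land mask
#'
#' @param biomes A [biome_fractions()].
#' @param mask Logical land mask.
#' @param weights Optional [area_weights()].
#' @return Named fractions summing to 1.
#' @export
biome_area_fractions <- function(biomes, mask = NULL, weights = NULL) {
  if (is.null(weights)) weights <- area_weights(biomes$grid)
  if (is.null(mask)) mask <- matrix(TRUE, biomes$grid$nlat, biomes$grid$nlon)
  a <- vapply(seq_along(biomes$labels), function(j) {
    sum((biomes$fractions[j, , ] * weights$values)[mask])
  }, 0)
  stats::setNames(a / sum(a), biomes$labels)
}

#' Order-gamma ensemble weights from scores
#'
#' `W_i = max(score_i, 0)^gamma / sum_k max(score_k, 0)^gamma`. Negative
#' scores are floored at zero (a model anti-correlated with SIF gets no
#' weight); an error is raised if no score is positive.
#'
#' @param scores Numeric model scores.
#' @param gamma Positive order coefficient (1, 2 and 4 are the standard
#'   choices; larger gamma concentrates weight on the best model).
#' @return Named weights summing to 1.
#' @export
ensemble_weights <- function(scores, gamma = 2) {
  if (gamma <= 0) validation_error("gamma must be positive")
  s <- pmax(scores, 0)
  if (all(s <= 0)) {
    validation_error("no model has a positive score; ensemble undefined")
  }
  w <- s^gamma
  w / sum(w)
}

#' Weighted ensemble of model GPP cubes
#'
#' `GPP_ens(t, cell) = sum_i W_i GPP_i(t, cell)`. Weights learned on the
#' training window are applied across the full analysis window.
#'
#' @param models Named list of [gridded_cube()]s on a common grid/time.
#' @param W Weights aligned with `models` (summing to 1).
#' @return A `gridded_cube`.
#' @export
weighted_ensemble <- function(models, W) {
  if (length(models) != length(W)) {
    validation_error("weights must align with models")
  }
  ref <- models[[1]]
  for (m in models) {
    if (!grids_equal(m$grid, ref$grid)) validation_error("model grids differ")
    if (length(m$time) != length(ref$time) ||
        any(m$time != ref$time)) {
      missing <- setdiff(ref$time, m$time)
      validation_error(sprintf(
        "model time axes differ (e.g. missing steps: %s)",
        paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  acc <- array(0, dim(ref$values))
  for (i in seq_along(models)) acc <- acc + W[i] * models[[i]]$values
  mask <- Reduce(`&`, lapply(models, `[[`, "mask"))
  gridded_cube(acc, ref$time, ref$grid, units = ref$units, mask = mask,
               freq = ref$freq)
}

#' Unweighted (simple-mean) ensemble
#'
#' @param models Named list of [gridded_cube()]s.
#' @return A `gridded_cube`.
#' @export
unweighted_ensemble <- function(models) {
  weighted_ensemble(models, rep(1 / length(models), length(models)))
}

#' Score every model against SIF
#'
#' Convenience wrapper: per-biome correlations for each model, the biome
#' area fractions, and the resulting score vector.
#'
#' @inheritParams biome_correlations
#' @param models Named list of model GPP cubes.
#' @return List with `scores`, `correlations` (matrix model x biome),
#'   `area_fractions`.
#' @export
ensemble_scores <- function(models, sif, biomes, mode = "spatial",
                            training_years, weights = NULL) {
  if (is.null(weights)) weights <- area_weights(sif$grid)
  mask <- Reduce(`&`, lapply(models, `[[`, "mask")) & sif$mask
  a <- biome_area_fractions(biomes, mask, weights)
  rows <- lapply(models, biome_correlations, sif = sif, biomes = biomes,
                 mode = mode, training_years = training_years,
                 weights = weights)
  corr <- do.call(rbind, rows)
  scores <- vapply(rows, model_score, 0, a = a)
  list(scores = scores, correlations = corr, area_fractions = a)
}

#' Leave-one-model-out stability of the ensemble
#'
#' For each left-out model, weights are recomputed on the remaining M-1
#' models and the chosen statistic (time-mean annual GPP map or per-cell
#' GPP s.d. map) recomputed for both the weighted and the unweighted
#' ensemble. Returns the per-cell s.d. across the M replicates for each
#' method and their difference (weighted minus unweighted); a robust
#' weighting scheme yields smaller spread.
#'
#' @param models Named list (length >= 3) of model GPP cubes.
#' @param sif,biomes,training_years,weights As [ensemble_scores()].
#' @param gamma Weight order.
#' @param statistic `"annual_gpp"` or `"gpp_sd"`.
#' @return List of fields `weighted_sd`, `unweighted_sd`, `difference`.
#' @export
leave_one_out_stability <- function(models, sif, biomes, training_years,
                                    gamma = 2,
                                    statistic = c("annual_gpp", "gpp_sd"),
                                    weights = NULL) {
  statistic <- match.arg(statistic)
  M <- length(models)
  if (M < 3) validation_error("need at least 3 models")
  sc <- ensemble_scores(models, sif, biomes, mode = "spatial",
                        training_years = training_years, weights = weights)
  stat_map <- function(cube) {
    ann <- if (cube$freq == "monthly") to_annual(cube, "sum") else cube
    Y <- cube_matrix(ann)
    v <- if (statistic == "annual_gpp") colMeans(Y) else apply(Y, 2, sd_pop)
    matrix(v, cube$grid$nlat, cube$grid$nlon)
  }
  w_maps <- u_maps <- vector("list", M)
  for (i in seq_len(M)) {
    keep <- setdiff(seq_len(M), i)
    Wk <- ensemble_weights(sc$scores[keep], gamma)
    w_maps[[i]] <- stat_map(weighted_ensemble(models[keep], Wk))
    u_maps[[i]] <- stat_map(unweighted_ensemble(models[keep]))
  }
  per_cell_sd <- function(maps) {
    arr <- simplify2array(maps)  # [lat, lon, M]
    apply(arr, c(1, 2), sd_pop)
  }
  grid <- models[[1]]$grid
  mask <- Reduce(`&`, lapply(models, `[[`, "mask"))
  mk <- function(v) {
    v[!mask] <- NA_real_
    grid_field(v, grid, units = models[[1]]$units, mask = mask)
  }
  wsd <- per_cell_sd(w_maps)
  usd <- per_cell_sd(u_maps)
  list(weighted_sd = mk(wsd), unweighted_sd = mk(usd),
       difference = mk(wsd - usd), scores = sc$scores)
}
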