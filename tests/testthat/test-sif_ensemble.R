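# Helpers for constructed correlation fixtures ---------------------------

one_biome <- function(grid) {
  biome_fractions(array(1, c(1, grid$nlat, grid$nlon)), "all", grid)
}

test_that("perfect proportionality gives r = 1 in both modes", {
  w <- small_world()
  gpp <- w$gpp_monthly
  sif2 <- gpp
  sif2$values <- 0.5 * gpp$values   # GPP = 2 x SIF everywhere
  sif2$units <- "mW m-2 sr-1 nm-1"
  for (mode in c("spatial", "temporal")) {
    r <- biome_correlations(gpp, sif2, w$biomes, mode = mode,
                            training_years = 2007:2011)
    expect_equal(as.vector(r), rep(1, length(r)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("independent noise decorrelates at the Monte-Carlo null width", {
  grid <- grid_spec(seq(-49.5, 49.5, by = 1), seq(-49.5, 49.5, by = 1))
  yrs <- 2007:2011
  set.seed(99)
  mk <- function() {
    gridded_cube(array(rnorm(length(yrs) * 100 * 100), c(5, 100, 100)),
                 yrs, grid, units = "g C m-2 yr-1", freq = "annual")
  }
  r <- biome_correlations(mk(), mk(), one_biome(grid), mode = "spatial",
                          training_years = yrs)
  expect_lt(abs(unname(r)[1]), 0.05)  # null width ~ 1/sqrt(1e4)
})

test_that("fraction-weighted correlation equals the subset oracle", {
  grid <- flat_grid(4, 6)
  yrs <- 2007:2011
  set.seed(3)
  g <- array(rnorm(5 * 4 * 6, 100, 30), c(5, 4, 6))
  s <- array(rnorm(5 * 4 * 6, 1, 0.3), c(5, 4, 6))
  gpp <- gridded_cube(g, yrs, grid, units = "g C m-2 yr-1")
  sif <- gridded_cube(s, yrs, grid, units = "mW m-2 sr-1 nm-1")
  # 0/1 checkerboard membership
  checker <- (outer(1:4, 1:6, `+`) %% 2 == 0) + 0
  fr <- array(NA_real_, c(2, 4, 6))
  fr[1, , ] <- checker
  fr[2, , ] <- 1 - checker
  biomes <- biome_fractions(fr, c("A", "B"), grid)
  r <- biome_correlations(gpp, sif, biomes, mode = "spatial",
                          training_years = yrs)
  # oracle: weighted Pearson restricted to each biome's own cells
  w <- area_weights(grid)$values
  gm <- apply(g, c(2, 3), mean)
  sm <- apply(s, c(2, 3), mean)
  for (j in 1:2) {
    sel <- fr[j, , ] == 1
    # brute-force weighted moments on the subset
    ww <- w[sel] / sum(w[sel])
    mx <- sum(ww * gm[sel]); my <- sum(ww * sm[sel])
    num <- sum(ww * (gm[sel] - mx) * (sm[sel] - my))
    den <- sqrt(sum(ww * (gm[sel] - mx)^2) * sum(ww * (sm[sel] - my)^2))
    expect_equal(unname(r[j]), num / den, tolerance = 1e-10)
  }
})

test_that("model_score averages by area with renormalisation", {
  expect_equal(model_score(c(a = 0.9), 1), 0.9)
  expect_equal(model_score(c(0.8, 0.4), c(0.75, 0.25)), 0.7)
  # all-equal correlations: score independent of a
  expect_equal(model_score(c(0.6, 0.6, 0.6), c(0.2, 0.3, 0.5)), 0.6)
  # undefined entries excluded with renormalised areas
  expect_equal(model_score(c(0.8, NA, 0.4), c(0.5, 0.3, 0.2)),
               (0.5 * 0.8 + 0.2 * 0.4) / 0.7)
  expect_error(model_score(c(NA_real_, NA_real_), c(0.5, 0.5)),
               class = "gppiav_validation_error")
})

test_that("ensemble weights follow the order-gamma power rule", {
  expect_equal(unname(ensemble_weights(c(0.8, 0.4), 2)), c(0.8, 0.2))
  expect_equal(unname(ensemble_weights(rep(0.37, 5), 4)), rep(0.2, 5))
  # top model dominates as gamma grows
  w_big <- ensemble_weights(c(0.9, 0.8, 0.5), 200)
  expect_gt(w_big[1], 0.999999)
  # negative scores floored at zero
  expect_equal(unname(ensemble_weights(c(0.5, -0.3), 1)), c(1, 0))
  expect_error(ensemble_weights(c(-0.1, -0.5), 2),
               class = "gppiav_validation_error")
  expect_error(ensemble_weights(c(0.5, 0.5), 0),
               class = "gppiav_validation_error")
  # monotonicity: raising one score never decreases its weight
  set.seed(8)
  for (k in 1:50) {
    s <- runif(6)
    g <- sample(c(1, 2, 4), 1)
    i <- sample(6, 1)
    s2 <- s; s2[i] <- s2[i] + runif(1)
    expect_gte(ensemble_weights(s2, g)[i] + 1e-12,
               ensemble_weights(s, g)[i])
  }
})

test_that("weighted and unweighted ensembles satisfy their algebra", {
  w <- small_world()
  models <- lapply(w$models, to_annual, method = "sum")
  M <- length(models)
  sel <- c(1, rep(0, M - 1))
  expect_equal(weighted_ensemble(models, sel)$values, models[[1]]$values,
               tolerance = 1e-12)
  W <- rep(1 / M, M)
  expect_equal(weighted_ensemble(models, W)$values,
               unweighted_ensemble(models)$values, tolerance = 1e-12)
  # permutation invariance of the unweighted mean
  perm <- sample(M)
  expect_equal(unweighted_ensemble(models[perm])$values,
               unweighted_ensemble(models)$values, tolerance = 1e-12)
  # convexity: ensemble lies within the per-cell model envelope
  W2 <- ensemble_weights(seq_len(M), 2)
  ens <- weighted_ensemble(models, W2)$values
  lo <- Reduce(pmin, lapply(models, `[[`, "values"))
  hi <- Reduce(pmax, lapply(models, `[[`, "values"))
  expect_true(all(ens >= lo - 1e-9 & ens <= hi + 1e-9))
  # missing years
  short <- models
  short[[2]] <- select_years(models[[2]], 2000:2010)
  err <- tryCatch(weighted_ensemble(short, W), error = identity)
  expect_s3_class(err, "gppiav_validation_error")
  expect_match(conditionMessage(err), "2011")
})

test_that("score ranking recovers truth quality on the small world", {
  w <- small_world()
  sc <- ensemble_scores(w$models, w$sif, w$biomes,
                        training_years = w$config$training_years)
  expect_equal(cor(rank(-sc$scores), w$model_table$quality_rank,
                   method = "spearman"), 1)
  expect_true(all(abs(sc$correlations) <= 1, na.rm = TRUE))
  expect_equal(sum(sc$area_fractions), 1, tolerance = 1e-12)
})

test_that("leave-one-out stability: identical models give zero spread", {
  w <- small_world()
  base <- to_annual(w$models[[1]], "sum")
  clones <- list(a = base, b = base, c = base, d = base)
  loo <- leave_one_out_stability(clones, w$sif, w$biomes,
                                 training_years = w$config$training_years,
                                 gamma = 2, statistic = "annual_gpp")
  expect_true(all(abs(loo$weighted_sd$values) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(loo$unweighted_sd$values) < 1e-9, na.rm = TRUE))
  expect_identical(dim(loo$difference$values),
                   c(w$grid$nlat, w$grid$nlon))
})
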