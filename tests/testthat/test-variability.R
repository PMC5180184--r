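# A 1 x K equatorial strip where every cell is its own "class" and area
# weights are equal: integrated class series are proportional to the
# cell series, so contribution formulas can be checked by hand.
strip_fixture <- function(series_list) {
  K <- length(series_list)
  nt <- length(series_list[[1]])
  vals <- array(NA_real_, c(nt, 1, K))
  for (k in seq_len(K)) vals[, 1, k] <- series_list[[k]]
  cube <- gridded_cube(vals, 2000 + seq_len(nt) - 1,
                       grid_spec(0, seq(0, K - 1)),
                       units = "g C m-2 yr-1", freq = "annual")
  labels <- paste0("c", seq_len(K))
  classes <- list(classes = matrix(labels, 1, K), labels = labels,
                  boundaries = NULL, grid = cube$grid)
  list(cube = cube, classes = classes)
}

test_that("decompose_trend reproduces hand OLS on 3 points", {
  fx <- strip_fixture(list(c(3, 1, 2)))
  dec <- decompose_trend(fx$cube)
  expect_equal(dec$slope$values[1, 1], -0.5, tolerance = 1e-12)
  expect_equal(dec$anomalies$values[, 1, 1], c(0.5, -1, 0.5),
               tolerance = 1e-12)
  expect_equal(dec$iav_detrended$values[1, 1],
               sqrt(mean(c(0.5, -1, 0.5)^2)), tolerance = 1e-12)
})

test_that("decompose_trend handles exact lines and constants", {
  fx <- strip_fixture(list(1:10, rep(4, 10)))
  dec <- decompose_trend(fx$cube)
  expect_equal(dec$slope$values[1, 1], 1, tolerance = 1e-12)
  expect_equal(max(abs(dec$anomalies$values[, 1, 1])), 0,
               tolerance = 1e-10)
  expect_equal(dec$slope$values[1, 2], 0, tolerance = 1e-12)
  expect_equal(dec$iav_detrended$values[1, 2], 0, tolerance = 1e-12)
})

test_that("decompose_trend invariants hold on random cubes", {
  w <- small_world()
  dec <- decompose_trend(w$gpp)
  t <- w$gpp$time
  A <- matrix(dec$anomalies$values, length(t), w$grid$nlat * w$grid$nlon)
  sdv <- apply(A, 2, sd)
  nz <- which(sdv > 0)
  # anomalies average to ~0 per cell
  expect_lt(max(abs(colMeans(A)[nz]) / sdv[nz]), 1e-8)
  # residual orthogonality to time
  tc <- t - mean(t)
  expect_lt(max(abs(crossprod(tc, A)[nz]) /
                  (sqrt(sum(tc^2)) * sdv[nz] * length(t))), 1e-8)
  # equivariance: adding a linear ramp shifts the slope, not anomalies
  ramp <- w$gpp
  ramp$values <- ramp$values + 3.5 * rep(t - 2000, w$grid$nlat * w$grid$nlon)
  dec2 <- decompose_trend(ramp)
  expect_equal(dec2$slope$values, dec$slope$values + 3.5,
               tolerance = 1e-10)
  expect_equal(dec2$anomalies$values, dec$anomalies$values,
               tolerance = 1e-8)
})

test_that("IAV contributions match the projection oracle", {
  # toy 3-class table: x1 = (1,-1), x2 = (2,-2), x3 = (1,-1)
  fx <- strip_fixture(list(c(1, -1), c(2, -2), c(1, -1)))
  # (2 time points only; bypass decompose_trend, these are anomalies)
  out <- regional_contribution_iav(fx$cube, fx$classes)
  expect_equal(unname(out$fractions), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
  # single class covering everything
  fx1 <- strip_fixture(list(c(1, -2, 1)))
  expect_equal(unname(regional_contribution_iav(fx1$cube,
                                                fx1$classes)$fractions),
               1, tolerance = 1e-12)
  # identical series split contributions equally
  fx2 <- strip_fixture(list(c(1, -1, 0.5), c(1, -1, 0.5)))
  expect_equal(unname(regional_contribution_iav(fx2$cube,
                                                fx2$classes)$fractions),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_error(
    regional_contribution_iav(strip_fixture(list(c(0, 0, 0)))$cube,
                              strip_fixture(list(c(0, 0, 0)))$classes),
    class = "gppiav_validation_error")
})

test_that("contributions sum to one and merge additively", {
  set.seed(17)
  for (rep in 1:5) {
    K <- sample(3:6, 1)
    fx <- strip_fixture(lapply(seq_len(K), function(i) rnorm(8)))
    out <- regional_contribution_iav(fx$cube, fx$classes)
    expect_equal(sum(out$fractions), 1, tolerance = 1e-9)
    # merging two classes adds their contributions exactly
    merged <- fx$classes
    merged$classes[merged$classes == "c2"] <- "c1"
    merged$labels <- setdiff(merged$labels, "c2")
    out2 <- regional_contribution_iav(fx$cube, merged)
    expect_equal(unname(out2$fractions["c1"]),
                 unname(out$fractions["c1"] + out$fractions["c2"]),
                 tolerance = 1e-9)
    # trend contributions also close
    tr <- regional_contribution_trend(fx$cube, classes = fx$classes)
    expect_equal(sum(tr$fractions), 1, tolerance = 1e-9)
  }
})

test_that("trend contributions follow class slopes", {
  yrs <- 0:9
  fx <- strip_fixture(list(2 * yrs, 1 * yrs + 3, 1 * yrs - 2))
  out <- regional_contribution_trend(fx$cube, classes = fx$classes)
  expect_equal(unname(out$fractions), c(0.5, 0.25, 0.25),
               tolerance = 1e-10)
  fx2 <- strip_fixture(list(rep(1, 5), 0:4))
  out2 <- regional_contribution_trend(fx2$cube, classes = fx2$classes)
  expect_equal(unname(out2$fractions), c(0, 1), tolerance = 1e-10)
})

test_that("binned curves match hand computation and partition cells", {
  grid <- flat_grid(2, 5)
  x <- grid_field(matrix(c(1, 4, 11, 14, 21, 24, 31, 34, 41, 44), 2, 5),
                  grid, units = "g C m-2 yr-1")
  y <- grid_field(matrix(1:10, 2, 5), grid)
  out <- bin_by_value(x, y, width = 10)
  # cells fall pairwise into bins [0,10), [10,20), ...
  expect_equal(sum(out$n), 10)
  # equal-area grid: weighted mean ~ plain mean within each bin
  expect_equal(out$mean[1], mean(c(1, 2)), tolerance = 1e-6)
  expect_equal(out$mean[3], mean(c(5, 6)), tolerance = 1e-6)
  # constant map: every occupied aridity bin returns the constant
  const <- grid_field(matrix(7, 2, 5), grid)
  ai <- grid_field(matrix(seq(0.1, 1, length.out = 10), 2, 5), grid)
  outc <- bin_by_aridity(const, ai, edges = seq(0, 2, 0.25))
  occ <- !is.na(outc$mean)
  expect_true(all(abs(outc$mean[occ] - 7) < 1e-12))
  expect_true(all(abs(outc$sd[occ]) < 1e-9))
})
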