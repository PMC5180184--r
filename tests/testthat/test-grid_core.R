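test_that("grid_spec validates axes", {
  expect_s3_class(grid_spec(c(-45, 0, 45), c(0, 120, 240)), "grid_spec")
  expect_error(grid_spec(c(0, 1, 3), c(0, 1)),
               class = "gppiav_validation_error")  # non-uniform
  expect_error(grid_spec(c(0, 10), c(0, 200, 400)),
               class = "gppiav_validation_error")  # lon out of range
  expect_error(grid_spec(c(0, 0), c(0, 1)),
               class = "gppiav_validation_error")  # non-monotonic
})

test_that("area weights normalise, respect symmetry and cos ratio", {
  grid <- grid_spec(seq(-80, 80, by = 20), seq(-170, 170, by = 20))
  w <- area_weights(grid)
  expect_equal(sum(w$values), 1, tolerance = 1e-12)
  # symmetric about the equator
  expect_equal(w$values[1, 1], w$values[grid$nlat, 1], tolerance = 1e-12)
  # ratio of equator (lat 0) to lat 80 equals cos(0)/cos(80 deg) ~ 5.76
  i0 <- which(grid$lat == 0)
  i80 <- which(grid$lat == 80)
  expect_equal(w$values[i0, 1] / w$values[i80, 1],
               cos(0) / cos(80 * pi / 180), tolerance = 1e-12)
})

test_that("cube round-trips through the JSON grid format", {
  w <- small_world()
  path <- tempfile(fileext = ".json")
  write_cube(w$gpp, path, variable = "gpp")
  back <- read_cube(path, "gpp")
  expect_equal(back$values, w$gpp$values, tolerance = 1e-12)
  expect_identical(back$units, w$gpp$units)
  expect_equal(back$time, w$gpp$time)
  expect_equal(back$grid$lat, w$gpp$grid$lat, tolerance = 1e-12)
  expect_identical(length(back$time), length(w$gpp$time))
  expect_error(read_cube(path, "nope"), class = "gppiav_format_error")
  expect_error(read_cube(tempfile(), "gpp"), class = "gppiav_io_error")
})

test_that("missing-value cells are masked on read, land count preserved", {
  arr <- array(runif(2 * 4 * 6), c(2, 4, 6))
  arr[, 1, 1] <- NA  # ocean cell
  cube <- flat_cube(array(ifelse(is.na(arr), NA, arr), dim(arr)))
  path <- tempfile(fileext = ".json")
  write_cube(cube, path, variable = "x")
  # independent reader: count finite entries straight from the JSON
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- raw$variables$x$values
  fill <- raw$variables$x$fill_value
  n_live_file <- sum(abs(vals - fill) > abs(fill) * 1e-6)
  back <- read_cube(path, "x")
  expect_identical(sum(back$mask), 4L * 6L - 1L)
  expect_identical(sum(is.finite(back$values)), as.integer(n_live_file))
})

test_that("aggregate_fractions averages blocks and conserves globals", {
  # 4 x 4 fine grid near the equator, two classes
  grid <- grid_spec(seq(-1.5, 1.5, by = 1), seq(0, 3, by = 1))
  fr <- array(0, c(2, 4, 4))
  fr[1, , ] <- matrix(c(rep(1, 6), rep(0, 10)), 4, 4)  # class A on 6 cells
  fr[2, , ] <- 1 - fr[1, , ]
  bf <- biome_fractions(fr, c("A", "B"), grid)
  coarse <- aggregate_fractions(bf, 2)
  # block (1,1): cells (1:2, 1:2) hold A-fractions 1,1,1,1 -> 1
  expect_equal(coarse$fractions[1, 1, 1], 1, tolerance = 1e-9)
  # uniform single-class map is unchanged
  uni <- biome_fractions(array(c(1, 0), c(2, 4, 4))[, , , drop = FALSE],
                         c("A", "B"), grid)
  expect_equal(aggregate_fractions(uni, 2)$fractions[1, , ],
               matrix(1, 2, 2), tolerance = 1e-12)
  # area-weighted global fraction of every class conserved
  wf <- area_weights(grid)
  wc <- area_weights(coarse$grid)
  for (j in 1:2) {
    fine_tot <- sum(bf$fractions[j, , ] * wf$values)
    coarse_tot <- sum(coarse$fractions[j, , ] * wc$values)
    expect_equal(coarse_tot, fine_tot, tolerance = 1e-12)
  }
  # per-cell sums stay <= 1
  expect_true(all(apply(coarse$fractions, c(2, 3), sum) <= 1 + 1e-9))
  expect_error(aggregate_fractions(bf, 3),
               class = "gppiav_validation_error")
})

test_that("to_annual sums fluxes, averages states, rejects partial years", {
  months <- as.vector(t(outer(2001:2002 * 100, 1:12, `+`)))
  vals <- array(100, c(24, 2, 3))
  cube <- gridded_cube(vals, months,
                       grid_spec(c(-10, 10), c(0, 10, 20)),
                       units = "g C m-2 month-1", freq = "monthly")
  ann <- to_annual(cube, "sum")
  expect_equal(ann$time, c(2001, 2002))
  expect_true(all(ann$values == 1200))
  expect_true(all(to_annual(cube, "mean")$values == 100))
  # sum = 12 x mean, cell-wise, also with varying data
  cube$values[] <- rnorm(length(cube$values))
  expect_equal(to_annual(cube, "sum")$values,
               12 * to_annual(cube, "mean")$values, tolerance = 1e-12)
  # 11-month year
  part <- gridded_cube(vals[1:23, , , drop = FALSE], months[1:23],
                       cube$grid, units = "g C m-2 month-1",
                       freq = "monthly")
  err <- tryCatch(to_annual(part, "sum"), error = identity)
  expect_s3_class(err, "gppiav_validation_error")
  expect_match(conditionMessage(err), "missing months 12")
})

test_that("global_total integrates, converts and validates units", {
  grid <- flat_grid(3, 4)
  f <- grid_field(matrix(1000, 3, 4), grid, units = "g C m-2 yr-1")
  expect_equal(global_total(f, land_area = 1.2e14, petagrams = TRUE), 120)
  expect_equal(global_total(f, land_area = 1.2e14, petagrams = TRUE),
               2 * global_total(grid_field(f$values / 2, grid,
                                           units = f$units),
                                land_area = 1.2e14, petagrams = TRUE))
  z <- grid_field(matrix(0, 3, 4), grid, units = "mm")
  expect_equal(global_total(z, land_area = 1e14), 0)
  bad <- grid_field(matrix(1, 3, 4), grid, units = "furlongs")
  expect_error(global_total(bad), class = "gppiav_validation_error")
  expect_error(global_total(z, petagrams = TRUE),
               class = "gppiav_validation_error")
})
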