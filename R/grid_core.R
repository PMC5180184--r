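# Gridded data model shared by all pipeline stages.
#
# Conventions: cell-centre coordinates on a regular lat-lon grid; field
# matrices are [lat, lon]; cubes are [time, lat, lon]. Monthly time steps
# are encoded as integer year*100 + month (e.g. 200001); annual steps as
# the calendar year. Units are declared strings, validated against a small
# alias table and never silently converted.

UNIT_ALIASES <- list(
  gpp = c("g C m-2 yr-1", "gC m-2 yr-1", "g C m^-2 yr^-1", "gC/m2/yr"),
  gpp_month = c("g C m-2 month-1", "gC m-2 month-1"),
  water = c("mm", "mm yr-1", "mm month-1"),
  sif = c("mW m-2 sr-1 nm-1", "mW m^-2 sr^-1 nm^-1"),
  temperature = c("degC", "deg C", "C"),
  radiation = c("W m-2", "MJ m-2"),
  dimensionless = c("", "1", "-")
)

unit_class <- function(units) {
  for (cl in names(UNIT_ALIASES)) {
    if (units %in% UNIT_ALIASES[[cl]]) return(cl)
  }
  NA_character_
}

#' Define a regular latitude-longitude grid
#'
#' @param lat Cell-centre latitudes, degrees north, strictly monotonic and
#'   uniformly spaced (tolerance 1e-6 degrees), within \[-90, 90\].
#' @param lon Cell-centre longitudes, degrees east, strictly monotonic and
#'   uniformly spaced, within \[-180, 180) or \[0, 360).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(lat, lon) {
  check_axis <- function(x, name, lo, hi) {
    if (length(x) < 1 || any(!is.finite(x))) {
      validation_error(sprintf("%s axis must be finite and non-empty", name))
    }
    if (length(x) > 1) {
      d <- diff(x)
      if (any(d == 0) || length(unique(sign(d))) != 1) {
        validation_error(sprintf("%s axis must be strictly monotonic", name))
      }
      if (max(abs(d - d[1])) > 1e-6) {
        validation_error(sprintf("%s axis spacing is not uniform", name))
      }
    }
    if (min(x) < lo || max(x) > hi) {
      validation_error(sprintf("%s axis outside [%g, %g]", name, lo, hi))
    }
  }
  check_axis(lat, "lat", -90, 90)
  if (min(lon) >= -180 && max(lon) < 180) {
    lon_convention <- "[-180,180)"
  } else if (min(lon) >= 0 && max(lon) < 360) {
    lon_convention <- "[0,360)"
  } else {
    validation_error("lon axis must lie within [-180, 180) or [0, 360)")
  }
  check_axis(lon, "lon", -180, 360)
  structure(
    list(lat = as.double(lat), lon = as.double(lon),
         nlat = length(lat), nlon = length(lon),
         lon_convention = lon_convention),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g], lon %s\n",
              x$nlat, x$nlon, min(x$lat), max(x$lat), x$lon_convention))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nlat == b$nlat && a$nlon == b$nlon &&
    max(abs(a$lat - b$lat)) < tol && max(abs(a$lon - b$lon)) < tol
}

#' A single 2-D field on a grid
#'
#' @param values Numeric matrix `[nlat, nlon]`.
#' @param grid A [grid_spec()].
#' @param units Units string (declared, not converted).
#' @param mask Logical land mask, same shape; `FALSE` cells are ignored by
#'   all statistics. Defaults to finiteness of `values`.
#' @return A `grid_field` object.
#' @export
grid_field <- function(values, grid, units = "", mask = NULL) {
  values <- as.matrix(values)
  if (!inherits(grid, "grid_spec")) validation_error("grid must be a grid_spec")
  if (nrow(values) != grid$nlat || ncol(values) != grid$nlon) {
    validation_error(sprintf(
      "field shape [%d, %d] does not match grid [%d, %d]",
      nrow(values), ncol(values), grid$nlat, grid$nlon))
  }
  if (is.null(mask)) mask <- is.finite(values)
  mask <- matrix(as.logical(mask), grid$nlat, grid$nlon)
  if (any(mask & !is.finite(values))) {
    validation_error("unmasked field values must be finite")
  }
  structure(list(values = values, grid = grid, units = units, mask = mask),
            class = "grid_field")
}

#' A time-stacked gridded cube
#'
#' @param values Numeric array `[ntime, nlat, nlon]`.
#' @param time Integer time axis, strictly increasing: calendar years for
#'   `freq = "annual"`, `year*100 + month` for `freq = "monthly"`.
#' @param grid A [grid_spec()].
#' @param units Units string.
#' @param mask Logical land mask `[nlat, nlon]`, shared by all time steps.
#' @param freq `"annual"` or `"monthly"`.
#' @return A `gridded_cube` object.
#' @export
gridded_cube <- function(values, time, grid, units = "",
                         mask = NULL, freq = c("annual", "monthly")) {
  freq <- match.arg(freq)
  values <- as.array(values)
  if (length(dim(values)) != 3) validation_error("cube values must be 3-D")
  if (dim(values)[1] != length(time)) {
    validation_error("time axis length does not match cube")
  }
  if (dim(values)[2] != grid$nlat || dim(values)[3] != grid$nlon) {
    validation_error("cube spatial shape does not match grid")
  }
  time <- as.double(time)
  if (length(time) > 1 && any(diff(time) <= 0)) {
    validation_error("time axis must be strictly increasing with no duplicates")
  }
  if (freq == "monthly" && any(time %% 100 < 1 | time %% 100 > 12)) {
    validation_error("monthly time must be encoded year*100 + month")
  }
  if (is.null(mask)) {
    mask <- apply(is.finite(values), c(2, 3), all)
  }
  mask <- matrix(as.logical(mask), grid$nlat, grid$nlon)
  structure(list(values = values, time = time, grid = grid, units = units,
                 mask = mask, freq = freq),
            class = "gridded_cube")
}

#' @export
print.gridded_cube <- function(x, ...) {
  cat(sprintf("<gridded_cube> %s, %d %s steps on %d x %d grid [%s]\n",
              if (nzchar(x$units)) x$units else "unitless",
              length(x$time), x$freq, x$grid$nlat, x$grid$nlon,
              paste(range(x$time), collapse = "..")))
  invisible(x)
}

# Extract the [lat, lon] field at one time index as a grid_field.
cube_slice <- function(cube, i, units = cube$units) {
  v <- cube$values[i, , , drop = TRUE]
  v <- matrix(v, cube$grid$nlat, cube$grid$nlon)
  v[!cube$mask] <- NA_real_
  grid_field(v, cube$grid, units = units, mask = cube$mask)
}

# Time-mean map over (a subset of) the cube's steps.
cube_time_mean <- function(cube, steps = seq_along(cube$time)) {
  v <- apply(cube$values[steps, , , drop = FALSE], c(2, 3), mean)
  v[!cube$mask] <- NA_real_
  grid_field(v, cube$grid, units = cube$units, mask = cube$mask)
}

cube_years <- function(cube) {
  if (cube$freq == "annual") cube$time else unique(cube$time %/% 100)
}

#' Subset a cube to the given calendar years
#'
#' @param cube A [gridded_cube()].
#' @param years Calendar years to keep (monthly cubes keep all months of
#'   those years).
#' @return A `gridded_cube`.
#' @export
select_years <- function(cube, years) {
  yr <- if (cube$freq == "annual") cube$time else cube$time %/% 100
  keep <- yr %in% years
  if (!any(keep)) validation_error("no time steps in the requested years")
  gridded_cube(cube$values[keep, , , drop = FALSE], cube$time[keep],
               cube$grid, units = cube$units, mask = cube$mask,
               freq = cube$freq)
}

#' Per-cell relative area weights
#'
#' Relative cell area proportional to the cosine of the cell-centre
#' latitude, normalised so the sum over all cells (land and ocean) is 1.
#' At 0.5 degrees this approximates exact spherical band areas to better
#' than 0.01\%.
#'
#' @param grid A [grid_spec()].
#' @return A `grid_field` of weights summing to 1.
#' @export
area_weights <- function(grid) {
  w <- matrix(cos(grid$lat * pi / 180), grid$nlat, grid$nlon)
  w <- w / sum(w)
  grid_field(w, grid, units = "")
}

#' Aggregate biome fractions to a coarser grid
#'
#' Coarse-cell fraction of each class is the area-weighted mean of the
#' `factor` x `factor` block of fine-cell fractions, mirroring the
#' recalculation of per-biome area proportions when land cover is brought
#' to the analysis resolution.
#'
#' @param fractions A [biome_fractions()] on the fine grid.
#' @param factor Integer block size; fine grid dimensions must divide by it.
#' @return A `biome_fractions` on the coarse grid.
#' @export
aggregate_fractions <- function(fractions, factor) {
  grid <- fractions$grid
  if (grid$nlat %% factor != 0 || grid$nlon %% factor != 0) {
    validation_error(sprintf(
      "grid %d x %d not divisible by factor %d", grid$nlat, grid$nlon, factor))
  }
  nlat_c <- grid$nlat %/% factor
  nlon_c <- grid$nlon %/% factor
  wlat <- cos(grid$lat * pi / 180)
  J <- dim(fractions$fractions)[1]
  out <- array(NA_real_, c(J, nlat_c, nlon_c))
  ilat <- (seq_len(grid$nlat) - 1) %/% factor + 1
  ilon <- (seq_len(grid$nlon) - 1) %/% factor + 1
  wmat <- matrix(wlat, grid$nlat, grid$nlon)
  for (j in seq_len(J)) {
    num <- fractions$fractions[j, , ] * wmat
    num_c <- t(rowsum(t(rowsum(num, ilat)), ilon))
    den_c <- t(rowsum(t(rowsum(wmat, ilat)), ilon))
    out[j, , ] <- num_c / den_c
  }
  lat_c <- colMeans(matrix(grid$lat, factor, nlat_c))
  lon_c <- colMeans(matrix(grid$lon, factor, nlon_c))
  biome_fractions(out, fractions$labels, grid_spec(lat_c, lon_c))
}

#' Per-cell fractional biome cover
#'
#' @param fractions Array `[J, nlat, nlon]` of fractional cover for J biome
#'   classes; each value in \[0, 1\] and per-cell sums at most 1 (+1e-6).
#' @param labels Character labels for the J classes.
#' @param grid A [grid_spec()].
#' @return A `biome_fractions` object.
#' @export
biome_fractions <- function(fractions, labels, grid) {
  fractions <- as.array(fractions)
  if (length(dim(fractions)) != 3) {
    validation_error("fractions must be [J, nlat, nlon]")
  }
  if (dim(fractions)[1] != length(labels)) {
    validation_error("labels length must match the biome axis")
  }
  if (dim(fractions)[2] != grid$nlat || dim(fractions)[3] != grid$nlon) {
    validation_error("fractions spatial shape does not match grid")
  }
  if (any(fractions < -1e-12 | fractions > 1 + 1e-12, na.rm = TRUE)) {
    validation_error("biome fractions must lie in [0, 1]")
  }
  sums <- apply(fractions, c(2, 3), sum)
  if (any(sums > 1 + 1e-6, na.rm = TRUE)) {
    validation_error("per-cell biome fractions must sum to at most 1")
  }
  structure(list(fractions = fractions, labels = labels, grid = grid),
            class = "biome_fractions")
}

#' Aggregate a monthly cube to annual
#'
#' Fluxes (GPP, precipitation, ET) are summed over months; state-like
#' quantities and SIF are averaged. Only whole calendar years are allowed.
#'
#' @param cube A monthly [gridded_cube()].
#' @param method `"sum"` or `"mean"`.
#' @return An annual `gridded_cube`.
#' @export
to_annual <- function(cube, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (cube$freq != "monthly") {
    validation_error("to_annual expects a monthly cube")
  }
  years <- cube$time %/% 100
  months <- cube$time %% 100
  uy <- sort(unique(years))
  missing <- lapply(uy, function(y) setdiff(1:12, months[years == y]))
  bad <- which(lengths(missing) > 0)
  if (length(bad)) {
    validation_error(sprintf(
      "partial years: %s",
      paste(sprintf("%d (missing months %s)", uy[bad],
                    vapply(missing[bad], paste, "", collapse = ",")),
            collapse = "; ")))
  }
  out <- array(NA_real_, c(length(uy), cube$grid$nlat, cube$grid$nlon))
  for (k in seq_along(uy)) {
    sl <- cube$values[years == uy[k], , , drop = FALSE]
    out[k, , ] <- apply(sl, c(2, 3), if (method == "sum") sum else mean)
  }
  gridded_cube(out, uy, cube$grid, units = cube$units, mask = cube$mask,
               freq = "annual")
}

#' Area-weighted land integral of a field
#'
#' Multiplies the area-weighted land mean of a per-area flux by the total
#' land area, e.g. turning g C m-2 yr-1 into a global total in Pg C yr-1.
#'
#' @param field A [grid_field()] with units in the GPP or water alias table.
#' @param weights Optional [area_weights()] field (computed if omitted).
#' @param land_area Total land area in m^2 represented by the masked cells.
#' @param petagrams If `TRUE`, convert g C to Pg C (factor 1e-15); only
#'   valid for carbon-flux units.
#' @return Scalar total.
#' @export
global_total <- function(field, weights = NULL, land_area = 1.2e14,
                         petagrams = FALSE) {
  cl <- unit_class(field$units)
  if (is.na(cl) || !(cl %in% c("gpp", "gpp_month", "water"))) {
    validation_error(sprintf(
      "global_total needs a flux field (g C m-2 yr-1 or mm); got units '%s'",
      field$units))
  }
  if (petagrams && !(cl %in% c("gpp", "gpp_month"))) {
    validation_error("petagram conversion only applies to carbon fluxes")
  }
  if (is.null(weights)) weights <- area_weights(field$grid)
  keep <- field$mask & is.finite(field$values)
  wm <- sum(field$values[keep] * weights$values[keep]) /
    sum(weights$values[keep])
  total <- wm * land_area
  if (petagrams) total <- total * 1e-15
  total
}
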