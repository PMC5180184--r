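# Self-describing plain-text gridded I/O.
#
# NetCDF bindings are not available in the supported toolchain, so cubes
# are serialised to a JSON container that mirrors CF conventions:
# coordinate variables (lat, lon, time), per-variable attributes
# (units, long_name), an explicit _FillValue sentinel for masked cells,
# and a format tag. One file holds one or more named variables on a
# shared grid and time axis.

GRID_FORMAT <- "gppiav-grid-1"
FILL_VALUE <- -9.969209968386869e36  # CF default float fill

#' Write a gridded cube to a self-describing JSON file
#'
#' @param cube A [gridded_cube()].
#' @param path Output path.
#' @param variable Variable name stored in the file.
#' @param long_name Optional descriptive attribute.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, variable = "value", long_name = variable) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    io_error(sprintf("cannot write to '%s'", path))
  }
  v <- cube$values
  for (i in seq_along(cube$time)) {
    sl <- v[i, , ]
    sl[!cube$mask | !is.finite(sl)] <- FILL_VALUE
    v[i, , ] <- sl
  }
  obj <- list(
    format = GRID_FORMAT,
    lat = cube$grid$lat,
    lon = cube$grid$lon,
    time = cube$time,
    freq = cube$freq,
    variables = stats::setNames(list(list(
      units = cube$units,
      long_name = long_name,
      fill_value = FILL_VALUE,
      dims = dim(v),
      values = as.vector(v)
    )), variable)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a gridded cube from a file written by [write_cube()]
#'
#' Fill-value cells are masked; land cell counts are preserved.
#'
#' @param path Input path.
#' @param variable Variable name to read.
#' @return A [gridded_cube()].
#' @export
read_cube <- function(path, variable = "value") {
  if (!file.exists(path)) io_error(sprintf("file '%s' does not exist", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    format_error(sprintf("'%s' is not a %s file: %s",
                                         path, GRID_FORMAT, conditionMessage(e)))
                  })
  if (is.null(obj$format) || obj$format != GRID_FORMAT) {
    format_error(sprintf("'%s' is not a %s file", path, GRID_FORMAT))
  }
  if (is.null(obj$variables[[variable]])) {
    format_error(sprintf(
      "variable '%s' not found in '%s' (has: %s)", variable, path,
      paste(names(obj$variables), collapse = ", ")))
  }
  var <- obj$variables[[variable]]
  values <- array(as.double(var$values), dim = as.integer(var$dims))
  fill <- var$fill_value
  values[abs(values - fill) < abs(fill) * 1e-6] <- NA_real_
  grid <- grid_spec(as.double(obj$lat), as.double(obj$lon))
  mask <- apply(is.finite(values), c(2, 3), all)
  gridded_cube(values, as.double(obj$time), grid,
               units = if (is.null(var$units)) "" else var$units,
               mask = mask, freq = obj$freq)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
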