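# Trend / detrended-anomaly decomposition of annual series, IAV maps,
# per-aridity-class contributions to global detrended variability and to
# the global trend, and binned-curve summaries.

#' Per-cell linear trend and detrended anomalies
#'
#' Ordinary least squares of each cell's annual series against calendar
#' year. Anomalies are the residuals; IAV is returned both as the
#' population standard deviation of the residuals (`iav_detrended`) and of
#' the raw annual values (`iav_raw`).
#'
#' @param cube An annual [gridded_cube()] with at least 3 years.
#' @return List with `slope`, `intercept`, `anomalies` (cube),
#'   `iav_detrended`, `iav_raw` (fields).
#' @export
decompose_trend <- function(cube) {
  if (cube$freq != "annual") validation_error("decompose_trend expects an annual cube")
  t <- cube$time
  nt <- length(t)
  if (nt < 3) validation_error("need at least 3 years")
  if (sd_pop(t) == 0) validation_error("time axis is constant")
  tc <- t - mean(t)
  stt <- sum(tc^2)
  grid <- cube$grid
  Y <- matrix(cube$values, nt, grid$nlat * grid$nlon)  # [time, cell]
  slope <- as.vector(crossprod(tc, Y)) / stt
  ybar <- colMeans(Y)
  fitted <- outer(tc, slope) + matrix(ybar, nt, length(ybar), byrow = TRUE)
  resid <- Y - fitted
  iav_det <- sqrt(colMeans(resid^2))
  iav_raw <- sqrt(colMeans(sweep(Y, 2, ybar)^2))
  shape <- c(grid$nlat, grid$nlon)
  mk_field <- function(v, units = cube$units) {
    m <- matrix(v, shape[1], shape[2])
    m[!cube$mask] <- NA_real_
    grid_field(m, grid, units = units, mask = cube$mask)
  }
  list(
    slope = mk_field(slope),
    intercept = mk_field(ybar - slope * mean(t)),
    anomalies = gridded_cube(array(resid, c(nt, shape)), t, grid,
                             units = cube$units, mask = cube$mask,
                             freq = "annual"),
    iav_detrended = mk_field(iav_det),
    iav_raw = mk_field(iav_raw)
  )
}

# Area-integrate a cube to one series per aridity class (and the global
# series). Weights are relative areas; multiply by land_area to get
# absolute integrals.
class_series <- function(cube, classes, weights = NULL, land_area = 1) {
  if (is.null(weights)) weights <- area_weights(cube$grid)
  labels <- classes$labels
  cl <- match(as.vector(as.character(classes$classes)), labels)
  nt <- length(cube$time)
  Y <- matrix(cube$values, nt, cube$grid$nlat * cube$grid$nlon)
  w <- as.vector(weights$values)
  keep <- as.vector(cube$mask) & !is.na(cl)
  out <- matrix(0, nt, length(labels), dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    idx <- which(keep & cl == j)
    if (length(idx)) {
      out[, j] <- Y[, idx, drop = FALSE] %*% w[idx] * land_area
    }
  }
  out
}

#' Per-class contributions to global detrended variability
#'
#' Classes' area-integrated anomaly series \eqn{x_{j,t}} are projected on
#' the global series \eqn{X_t = \sum_j x_{j,t}}:
#' \deqn{f_j = \sum_t x_{j,t} X_t / \sum_t X_t^2}
#' which is exactly additive (\eqn{\sum_j f_j = 1}) and reduces to
#' variance shares when regional series are uncorrelated. The plain
#' variance-share alternative is available via `method`.
#'
#' @param anomalies Detrended annual anomaly [gridded_cube()].
#' @param classes Classification from [classify_aridity()].
#' @param weights Optional [area_weights()].
#' @param method `"projection"` (default) or `"variance_share"`.
#' @return List with `fractions` (named, summing to 1 for projection),
#'   `class_series` (matrix time x class), `global_series`.
#' @export
regional_contribution_iav <- function(anomalies, classes, weights = NULL,
                                      method = c("projection",
                                                 "variance_share")) {
  method <- match.arg(method)
  xs <- class_series(anomalies, classes, weights)
  X <- rowSums(xs)
  if (all(abs(X) < .Machine$double.eps)) {
    validation_error("global anomaly series is identically zero")
  }
  f <- if (method == "projection") {
    colSums(xs * X) / sum(X^2)
  } else {
    v <- apply(xs, 2, function(x) sum((x - mean(x))^2))
    v / sum(v)
  }
  list(fractions = f, class_series = xs, global_series = X,
       method = method)
}

#' Per-class contributions to the global trend
#'
#' OLS slope of each class's area-integrated annual series; the fraction
#' is the class slope over the global slope (the sum of class slopes, by
#' linearity of OLS).
#'
#' @param series Matrix `[time, class]` of area-integrated annual values,
#'   or an annual cube plus `classes`.
#' @param time Calendar years matching rows of `series`.
#' @param classes,weights Used when `series` is a cube.
#' @return List with `fractions`, `slopes`, `global_slope`.
#' @export
regional_contribution_trend <- function(series, time = NULL, classes = NULL,
                                        weights = NULL) {
  if (inherits(series, "gridded_cube")) {
    time <- series$time
    series <- class_series(series, classes, weights)
  }
  if (is.null(time)) validation_error("time axis required")
  if (nrow(series) < 3) validation_error("need at least 3 years")
  tc <- time - mean(time)
  slopes <- as.vector(crossprod(tc, series)) / sum(tc^2)
  names(slopes) <- colnames(series)
  gs <- sum(slopes)
  if (abs(gs) < .Machine$double.eps) {
    validation_error("global trend is zero; fractions undefined")
  }
  list(fractions = slopes / gs, slopes = slopes, global_slope = gs)
}

#' Bin a field by aridity index
#'
#' Area-weighted mean and population s.d. of `value` within AI bins.
#' Bins with fewer than 10 member cells are flagged.
#'
#' @param value,ai [grid_field()]s on a common mask.
#' @param edges Increasing bin edges (default 0.01-wide bins on \[0, 2\]).
#' @param weights Optional [area_weights()].
#' @return Data frame with bin centre, mean, sd, n, flagged.
#' @export
bin_by_aridity <- function(value, ai, edges = seq(0, 2, by = 0.01),
                           weights = NULL) {
  bin_field_by(value, ai, edges, weights)
}

#' Bin one field by the values of another
#'
#' Bins start at 0 with the given width (e.g. 10 g C m-2 yr-1 bins of GPP
#' IAV) and extend to cover the maximum of `x`.
#'
#' @param x,y [grid_field()]s on a common mask (`x` defines the bins).
#' @param width Bin width in `x` units.
#' @param weights Optional [area_weights()].
#' @return Data frame with bin centre, mean, sd, n, flagged.
#' @export
bin_by_value <- function(x, y, width = 10, weights = NULL) {
  hi <- max(x$values[x$mask], na.rm = TRUE)
  edges <- seq(0, width * ceiling(hi / width + 1e-12), by = width)
  bin_field_by(y, x, edges, weights)
}

bin_field_by <- function(value, by, edges, weights = NULL) {
  if (!grids_equal(value$grid, by$grid)) {
    validation_error("fields must share a grid")
  }
  if (is.null(weights)) weights <- area_weights(value$grid)
  mask <- value$mask & by$mask & is.finite(value$values) &
    is.finite(by$values)
  if (!any(mask)) validation_error("no overlapping unmasked cells")
  v <- value$values[mask]
  b <- by$values[mask]
  w <- weights$values[mask]
  idx <- findInterval(b, edges, rightmost.closed = FALSE, left.open = FALSE)
  nb <- length(edges) - 1
  res <- data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_center = (edges[-1] + edges[-length(edges)]) / 2
  )
  stats_list <- lapply(seq_len(nb), function(k) {
    sel <- idx == k
    if (!any(sel)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    weighted_mean_sd(v[sel], w[sel])
  })
  sm <- do.call(rbind, stats_list)
  res$mean <- sm[, "mean"]
  res$sd <- sm[, "sd"]
  res$n <- sm[, "n"]
  res$flagged <- res$n < 10
  res
}
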