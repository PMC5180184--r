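# Budyko framework: analytical evapotranspiration curve ET(P, PET, n),
# closed-form sensitivities, first-order propagation of interannual
# variability from precipitation, aridity-index computation and the UNEP
# aridity classification.

ARIDITY_BOUNDS <- c(0.05, 0.2, 0.5, 0.65)
ARIDITY_CLASSES <- c("hyper-arid", "arid", "semi-arid", "dry sub-humid",
                     "humid")

#' Analytical Budyko evapotranspiration
#'
#' The Budyko hypothesis states that long-term ET/P depends only on the
#' demand/supply ratio PET/P. The analytical one-parameter solution used
#' here is
#' \deqn{ET = \frac{P \cdot PET}{(P^n + PET^n)^{1/n}}}
#' where the landscape exponent `n` encodes vegetation and catchment
#' characteristics (typical global range 0.5-2). The closely related Fu
#' form \eqn{ET = P(1 + x - (1 + x^n)^{1/n})}, \eqn{x = PET/P}, is
#' available for sensitivity analysis via `form = "fu"`.
#'
#' Evaluation factors out `max(P, PET)` before exponentiation so extreme
#' aridity ratios stay numerically stable.
#'
#' @param P Precipitation (mm yr-1), non-negative.
#' @param PET Potential evapotranspiration (mm yr-1), non-negative.
#' @param n Landscape exponent, positive. Recycled across `P`/`PET`.
#' @param form `"choudhury"` (default, the solution above) or `"fu"`.
#' @return ET (mm yr-1), bounded by `0 <= ET <= min(P, PET)`.
#' @export
budyko_et <- function(P, PET, n, form = c("choudhury", "fu")) {
  form <- match.arg(form)
  if (any(n <= 0)) validation_error("Budyko exponent n must be positive")
  if (any(P < 0, na.rm = TRUE) || any(PET < 0, na.rm = TRUE)) {
    validation_error("P and PET must be non-negative")
  }
  k <- pmax(P, PET)
  m <- pmin(P, PET)
  r <- ifelse(k > 0, m / k, 0)
  if (form == "choudhury") {
    # ET = P*PET/(P^n+PET^n)^(1/n) = min/(1 + r^n)^(1/n), r = min/max
    et <- ifelse(k > 0, m / (1 + r^n)^(1 / n), 0)
  } else {
    x <- ifelse(P > 0, PET / P, Inf)
    et <- ifelse(P > 0,
                 P * (1 + x - (1 + x^n)^(1 / n)),
                 0)
    # Fu's form in the PET -> Inf limit tends to P; guard overflow
    et <- ifelse(is.finite(et), et, pmin(P, PET))
  }
  pmin(pmax(et, 0), pmin(P, PET))
}

#' Closed-form Budyko sensitivities
#'
#' Partial derivatives of the analytical solution:
#' \deqn{\partial ET/\partial P = PET^{n+1} / (P^n + PET^n)^{(n+1)/n}}
#' and symmetrically for PET. Both lie in (0, 1); the precipitation
#' sensitivity tends to 1 as the aridity index P/PET tends to 0 (every mm
#' of rain evaporates) and to 0 as P/PET grows (energy-limited).
#'
#' @inheritParams budyko_et
#' @return List with elements `dET_dP`, `dET_dPET`, and `limit_flag`
#'   (`TRUE` where P or PET was zero and the limit value was returned).
#' @export
budyko_sensitivity <- function(P, PET, n) {
  if (any(n <= 0)) validation_error("Budyko exponent n must be positive")
  k <- pmax(P, PET)
  m <- pmin(P, PET)
  r <- ifelse(k > 0, m / k, 0)
  # denominator (P^n+PET^n)^((n+1)/n) = max^(n+1) * (1+r^n)^((n+1)/n)
  denom_scaled <- (1 + r^n)^((n + 1) / n)
  dP <- (PET / k)^(n + 1) / denom_scaled
  dPET <- (P / k)^(n + 1) / denom_scaled
  zeroP <- P == 0
  zeroPET <- PET == 0
  dP[zeroP] <- 1
  dPET[zeroP] <- 0
  dPET[zeroPET] <- 1
  dP[zeroPET] <- 0
  list(dET_dP = dP, dET_dPET = dPET, limit_flag = zeroP | zeroPET)
}

#' First-order interannual ET variability from climate variability
#'
#' Delta-method propagation through the Budyko curve: the contribution of
#' precipitation is \eqn{|\partial ET/\partial P| \sigma_P} evaluated at
#' the climatological means, likewise for PET, combined in quadrature
#' under independence. Components are returned separately so the claim
#' that the PET contribution is negligible can be checked rather than
#' assumed.
#'
#' @param P_mean,PET_mean Climatological means (mm yr-1), positive.
#' @param sigma_P,sigma_PET Interannual standard deviations (mm yr-1).
#' @param n Landscape exponent.
#' @return List with `sigma_ET`, `contribution_P`, `contribution_PET`.
#' @export
predict_et_iav <- function(P_mean, sigma_P, PET_mean, sigma_PET = 0, n = 1.5) {
  if (any(P_mean <= 0, na.rm = TRUE) || any(PET_mean <= 0, na.rm = TRUE)) {
    validation_error("climatological means must be positive")
  }
  if (any(sigma_P < 0, na.rm = TRUE) || any(sigma_PET < 0, na.rm = TRUE)) {
    validation_error("standard deviations must be non-negative")
  }
  s <- budyko_sensitivity(P_mean, PET_mean, n)
  cP <- abs(s$dET_dP) * sigma_P
  cPET <- abs(s$dET_dPET) * sigma_PET
  list(sigma_ET = sqrt(cP^2 + cPET^2),
       contribution_P = cP,
       contribution_PET = cPET)
}

#' Aridity index from climatological fields
#'
#' AI = mean annual precipitation / mean annual potential
#' evapotranspiration, cell-wise. Land cells with non-positive PET are
#' masked with a warning naming the count.
#'
#' @param P_mean,PET_mean Climatological-mean [grid_field()]s on a common
#'   grid.
#' @return A dimensionless `grid_field`.
#' @export
aridity_index <- function(P_mean, PET_mean) {
  if (!grids_equal(P_mean$grid, PET_mean$grid)) {
    validation_error("P and PET fields must share a grid")
  }
  mask <- P_mean$mask & PET_mean$mask
  bad <- mask & !(PET_mean$values > 0)
  if (any(bad)) {
    warning(sprintf("masked %d land cells with non-positive PET", sum(bad)))
    mask <- mask & !bad
  }
  ai <- P_mean$values / PET_mean$values
  ai[!mask] <- NA_real_
  grid_field(ai, P_mean$grid, units = "", mask = mask)
}

#' Classify cells by aridity
#'
#' UNEP climatological classes on the aridity index AI = P/PET with
#' half-open boundaries `[lower, upper)`:
#' hyper-arid `[0, 0.05)`, arid `[0.05, 0.2)`, semi-arid `[0.2, 0.5)`,
#' dry sub-humid `[0.5, 0.65)`, humid `[0.65, Inf)`. Drylands are all
#' classes below AI 0.65.
#'
#' @param ai Aridity index: a [grid_field()] or numeric vector.
#' @param boundaries Increasing class boundaries (default UNEP table).
#' @param weights Optional [area_weights()] field used for class area
#'   fractions when `ai` is a field.
#' @return For field input, a list with `classes` (factor matrix wrapped in
#'   the input grid), `boundaries`, `labels` and `area_fractions`; for
#'   vector input, a factor.
#' @export
classify_aridity <- function(ai, boundaries = ARIDITY_BOUNDS,
                             weights = NULL) {
  if (any(diff(boundaries) <= 0)) {
    validation_error("class boundaries must be increasing")
  }
  labels <- if (length(boundaries) == length(ARIDITY_BOUNDS)) {
    ARIDITY_CLASSES
  } else {
    paste0("class", seq_len(length(boundaries) + 1))
  }
  cut_one <- function(x) {
    cut(x, breaks = c(-Inf, boundaries, Inf), labels = labels,
        right = FALSE)
  }
  if (inherits(ai, "grid_field")) {
    if (any(ai$values[ai$mask] < 0)) {
      validation_error("aridity index must be non-negative")
    }
    cl <- cut_one(as.vector(ai$values))
    cl[!as.vector(ai$mask)] <- NA
    classes <- matrix(cl, ai$grid$nlat, ai$grid$nlon)
    if (is.null(weights)) weights <- area_weights(ai$grid)
    w <- weights$values[ai$mask]
    fr <- tapply(w, cl[as.vector(ai$mask)], sum)
    fr[is.na(fr)] <- 0
    fr <- fr / sum(fr)
    list(classes = classes, grid = ai$grid, labels = labels,
         boundaries = boundaries,
         area_fractions = stats::setNames(as.vector(fr), labels))
  } else {
    if (any(ai < 0, na.rm = TRUE)) {
      validation_error("aridity index must be non-negative")
    }
    cut_one(ai)
  }
}

#' Fit the Budyko exponent to (P, PET, ET) data
#'
#' Bracketed 1-D least squares for `n` on \[0.05, 20\] via
#' [stats::optimize()]. With fewer than 3 points the inverse problem is
#' under-determined and the result is flagged ambiguous.
#'
#' @param P,PET,ET Numeric vectors (annual or climatological), same length.
#' @param interval Search interval for `n`.
#' @return List with `n_hat`, `sse`, `converged`, `ambiguous`.
#' @export
fit_n <- function(P, PET, ET, interval = c(0.05, 20)) {
  keep <- is.finite(P) & is.finite(PET) & is.finite(ET)
  P <- P[keep]; PET <- PET[keep]; ET <- ET[keep]
  if (length(P) == 0) validation_error("no finite data to fit")
  sse <- function(n) sum((ET - budyko_et(P, PET, n))^2)
  opt <- stats::optimize(sse, interval = interval, tol = 1e-10)
  ambiguous <- length(P) < 3
  at_edge <- min(opt$minimum - interval[1], interval[2] - opt$minimum) < 1e-6
  list(n_hat = opt$minimum, sse = opt$objective,
       converged = !at_edge && !ambiguous, ambiguous = ambiguous)
}
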