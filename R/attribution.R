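# Climate attribution of GPP interannual variability: per-cell partial
# correlations with climate drivers, GPP-ET coupling (Pearson r and the
# regression slope beta, a water-use-efficiency proxy), and the
# sigma_GPP = beta * sigma_ET decomposition.

#' Partial correlation by the residual method
#'
#' Correlation between the OLS residuals of `y` on the controls and of
#' `x` on the controls; equivalent to the precision-matrix definition and
#' extends to any number of controls. The two-sided p-value uses the t
#' distribution with `N - 2 - k` degrees of freedom for `k` controls.
#'
#' @param y,x Numeric series.
#' @param controls Numeric vector, matrix or list of control series.
#' @return List with `estimate`, `p.value`, `n`, `df`. `estimate` is `NA`
#'   (flagged via `undefined`) for constant or collinear inputs.
#' @export
partial_correlation <- function(y, x, controls) {
  if (is.list(controls) && !is.data.frame(controls)) {
    controls <- do.call(cbind, controls)
  }
  C <- as.matrix(controls)
  keep <- is.finite(y) & is.finite(x) & apply(is.finite(C), 1, all)
  y <- y[keep]; x <- x[keep]; C <- C[keep, , drop = FALSE]
  k <- ncol(C)
  n <- length(y)
  undef <- list(estimate = NA_real_, p.value = NA_real_, n = n,
                df = n - 2 - k, undefined = TRUE)
  if (n < k + 3) return(undef)
  X <- cbind(1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(undef)  # collinear controls
  ry <- qr.resid(qx, y)
  rx <- qr.resid(qx, x)
  tol_y <- 1e-10 * (sd_pop(y) + abs(mean(y)))
  tol_x <- 1e-10 * (sd_pop(x) + abs(mean(x)))
  if (sd_pop(ry) <= tol_y || sd_pop(rx) <= tol_x) return(undef)
  rho <- stats::cor(ry, rx)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(estimate = rho, p.value = p, n = n, df = df, undefined = FALSE)
}

# Flatten an annual cube to a [time, cell] matrix and the land-cell index.
cube_matrix <- function(cube) {
  nt <- length(cube$time)
  matrix(cube$values, nt, cube$grid$nlat * cube$grid$nlon)
}

#' Per-cell partial-correlation attribution of GPP to climate drivers
#'
#' For every land cell, the partial correlation of annual GPP with each of
#' precipitation, temperature and shortwave radiation, controlling for the
#' other two, with a per-cell two-sided t test at level `alpha` (no
#' multiple-testing correction by default, `p_adjust = "BH"` optionally).
#'
#' @param gpp,P,T,SW Annual [gridded_cube()]s on a common grid and years.
#' @param alpha Significance level for the masks.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return List of fields `rho_P`, `rho_T`, `rho_SW`, matching p-value
#'   fields, significance masks `sig_P` etc., and `n_undefined`.
#' @export
climate_attribution <- function(gpp, P, T, SW, alpha = 0.05,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  cubes <- list(gpp = gpp, P = P, T = T, SW = SW)
  for (nm in names(cubes)) {
    if (!grids_equal(cubes[[nm]]$grid, gpp$grid) ||
        length(cubes[[nm]]$time) != length(gpp$time)) {
      validation_error(sprintf("cube '%s' not aligned with gpp", nm))
    }
  }
  mask <- gpp$mask & P$mask & T$mask & SW$mask
  G <- cube_matrix(gpp); Pm <- cube_matrix(P)
  Tm <- cube_matrix(T); Sm <- cube_matrix(SW)
  cells <- which(as.vector(mask))
  grid <- gpp$grid
  drivers <- c("P", "T", "SW")
  rho <- pval <- lapply(drivers, function(d) {
    matrix(NA_real_, grid$nlat, grid$nlon)
  })
  names(rho) <- names(pval) <- drivers
  n_undef <- 0L
  mats <- list(P = Pm, T = Tm, SW = Sm)
  for (cell in cells) {
    g <- G[, cell]
    xs <- lapply(mats, function(m) m[, cell])
    for (d in drivers) {
      ctrl <- do.call(cbind, xs[setdiff(drivers, d)])
      pc <- partial_correlation(g, xs[[d]], ctrl)
      if (pc$undefined) n_undef <- n_undef + 1L
      rho[[d]][cell] <- pc$estimate
      pval[[d]][cell] <- pc$p.value
    }
  }
  out <- list(n_undefined = n_undef, alpha = alpha)
  for (d in drivers) {
    pv <- pval[[d]]
    if (p_adjust == "BH") {
      pv[mask] <- stats::p.adjust(pv[mask], method = "BH")
    }
    out[[paste0("rho_", d)]] <- grid_field(rho[[d]], grid, "", mask)
    out[[paste0("p_", d)]] <- grid_field(pv, grid, "", mask)
    sig <- pv < alpha
    sig[!mask] <- NA
    out[[paste0("sig_", d)]] <- grid_field(sig + 0, grid, "", mask)
  }
  out
}

#' Per-cell GPP-ET coupling
#'
#' Pearson correlation and the OLS slope beta of GPP anomalies on ET
#' anomalies, per ET product, plus their across-product means. Where
#' water limits production, beta approximates the ecosystem water-use
#' efficiency (g C per mm). The identity `beta = r * sigma_GPP / sigma_ET`
#' links the slope to the correlation maps.
#'
#' @param gpp_anom Detrended annual GPP anomaly [gridded_cube()].
#' @param et_anom A single anomaly cube or named list of cubes (one per
#'   ET product) on the same grid/years.
#' @param ai Optional aridity-index [grid_field()]; when given, binned
#'   beta-vs-AI curves are returned per product.
#' @param ai_edges Bin edges for the AI curves.
#' @return List with per-product `beta`, `r`, `se` field lists, the
#'   across-product `beta_mean` and `r_mean` fields, and `curves`.
#' @export
gpp_et_coupling <- function(gpp_anom, et_anom, ai = NULL,
                            ai_edges = seq(0, 2, by = 0.1)) {
  if (inherits(et_anom, "gridded_cube")) et_anom <- list(et = et_anom)
  grid <- gpp_anom$grid
  nt <- length(gpp_anom$time)
  G <- cube_matrix(gpp_anom)
  Gc <- sweep(G, 2, colMeans(G))
  per <- lapply(et_anom, function(et) {
    if (!grids_equal(et$grid, grid) || length(et$time) != nt) {
      validation_error("ET cube not aligned with GPP")
    }
    E <- cube_matrix(et)
    Ec <- sweep(E, 2, colMeans(E))
    see <- colSums(Ec^2)
    sgg <- colSums(Gc^2)
    sge <- colSums(Gc * Ec)
    beta <- ifelse(see > 0, sge / see, NA_real_)
    r <- ifelse(see > 0 & sgg > 0, sge / sqrt(see * sgg), NA_real_)
    resid_var <- pmax(sgg - ifelse(see > 0, sge^2 / see, 0), 0) /
      pmax(nt - 2, 1)
    se <- ifelse(see > 0, sqrt(resid_var / see), NA_real_)
    mask <- gpp_anom$mask & et$mask &
      matrix(is.finite(beta) & is.finite(se), grid$nlat, grid$nlon)
    mk <- function(v, units = "") {
      m <- matrix(v, grid$nlat, grid$nlon)
      m[!mask] <- NA_real_
      grid_field(m, grid, units, mask)
    }
    list(beta = mk(beta, "g C mm-1"), r = mk(r), se = mk(se, "g C mm-1"))
  })
  avg_field <- function(what, units = "") {
    acc <- Reduce(`+`, lapply(per, function(p) {
      v <- p[[what]]$values
      v[is.na(v)] <- 0
      v
    }))
    cnt <- Reduce(`+`, lapply(per, function(p) !is.na(p[[what]]$values) + 0))
    m <- acc / cnt
    grid_field(m, grid, units, is.finite(m))
  }
  beta_mean <- avg_field("beta", "g C mm-1")
  r_mean <- avg_field("r")
  curves <- NULL
  if (!is.null(ai)) {
    curves <- lapply(names(per), function(nm) {
      cv <- bin_field_by(per[[nm]]$beta, ai, ai_edges)
      cv$product <- nm
      cv
    })
    curves <- do.call(rbind, curves)
  }
  list(products = per, beta_mean = beta_mean, r_mean = r_mean,
       curves = curves)
}

#' Compare predicted and actual GPP IAV
#'
#' The coupling decomposition predicts `sigma_GPP = |beta| * sigma_ET`.
#' Returns the predicted field, the per-cell ratio predicted/actual, and
#' an area-weighted summary by aridity class: the decomposition is
#' expected to hold (ratio near 1) only where GPP and ET are strongly
#' coupled, i.e. water-limited cells.
#'
#' @param beta Coupling-slope [grid_field()] (g C per mm).
#' @param sigma_et,sigma_gpp IAV fields (mm yr-1, g C m-2 yr-1).
#' @param classes Optional [classify_aridity()] result for the summary.
#' @param weights Optional [area_weights()].
#' @return List with `predicted`, `ratio` fields and `summary` data frame.
#' @export
decompose_gpp_iav <- function(beta, sigma_et, sigma_gpp, classes = NULL,
                              weights = NULL) {
  mask <- beta$mask & sigma_et$mask & sigma_gpp$mask
  pred <- abs(beta$values) * sigma_et$values
  ratio <- ifelse(sigma_gpp$values > 0, pred / sigma_gpp$values, NA_real_)
  pred[!mask] <- NA_real_
  ratio[!mask] <- NA_real_
  predicted <- grid_field(pred, beta$grid, sigma_gpp$units,
                          mask & is.finite(pred))
  ratio_f <- grid_field(ratio, beta$grid, "", mask & is.finite(ratio))
  summary <- NULL
  if (!is.null(classes)) {
    if (is.null(weights)) weights <- area_weights(beta$grid)
    cl <- matrix(match(as.vector(as.character(classes$classes)),
                       classes$labels),
                 nrow(classes$classes), ncol(classes$classes))
    rows <- lapply(seq_along(classes$labels), function(j) {
      sel <- !is.na(cl) & cl == j & ratio_f$mask
      st <- weighted_mean_sd(ratio[sel], weights$values[sel])
      data.frame(class = classes$labels[j], mean_ratio = st["mean"],
                 sd_ratio = st["sd"], n = st["n"], row.names = NULL)
    })
    summary <- do.call(rbind, rows)
  }
  list(predicted = predicted, ratio = ratio_f, summary = summary)
}

#' Correlation-vs-IAV binned curves
#'
#' Area-weighted mean and s.d. of each coupling/attribution coefficient
#' within GPP-IAV bins of the given width (default 10 g C m-2 yr-1).
#'
#' @param coef_maps Named list of coefficient [grid_field()]s (e.g.
#'   `rho_P`, `rho_T`, `rho_SW`, `r_ET`).
#' @param sigma_gpp GPP IAV [grid_field()].
#' @param width Bin width in `sigma_gpp` units.
#' @param weights Optional [area_weights()].
#' @return Long data frame with a `coefficient` column.
#' @export
coupling_vs_iav_curves <- function(coef_maps, sigma_gpp, width = 10,
                                   weights = NULL) {
  out <- lapply(names(coef_maps), function(nm) {
    cv <- bin_by_value(sigma_gpp, coef_maps[[nm]], width, weights)
    cv$coefficient <- nm
    cv
  })
  do.call(rbind, out)
}
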