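# Seeded synthetic planet with known ground truth.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: an aridity gradient covering all five UNEP classes;
# annual precipitation anomalies with a coefficient of variation that
# decreases from arid to humid climates; Budyko-consistent ET with a
# known per-cell landscape exponent n; water-limited GPP = WUE x ET plus
# a secular trend, radiation-driven GPP in humid cells; per-biome
# SIF proportional to GPP with additive retrieval-scale noise; and M
# model GPP cubes with known multiplicative bias and noise defining a
# ground-truth quality ranking. All noise is Gaussian (truncated where
# positivity is required) and independent across cells and years; every
# random field draws from its own (seed, name) stream.

#' Configuration of the synthetic world
#'
#' Defaults mirror the analysis set-up the package targets: a 2000-2011
#' analysis window with a 2007-2011 training window, 14 GPP models, a
#' Budyko exponent within 0.5-2, and SIF noise at the retrieval
#' uncertainty scale (0.1-0.4 mW m-2 sr-1 nm-1).
#'
#' @param nlat,nlon Grid size.
#' @param years Analysis years (whole calendar years).
#' @param training_years Ensemble training window.
#' @param n_biomes Number of biome classes J.
#' @param n_models Number of GPP models M.
#' @param seed Master seed; all streams derive from it.
#' @param ai_range Aridity-index range spanned by the longitude gradient.
#' @param pet_range Climatological PET range (mm yr-1) across latitude.
#' @param n_range Budyko exponent range; cells draw uniformly from it.
#' @param cv_p_coef CV of annual precipitation at aridity index 1.
#' @param cv_p_exponent Power-law decline of the precipitation CV with
#'   aridity index (CV = `cv_p_coef * AI^-cv_p_exponent`, capped).
#' @param cv_p_max Upper cap on the precipitation CV.
#' @param cv_pet CV of annual PET (much smaller than precipitation's).
#' @param et_noise_cv Relative s.d. of non-Budyko ET noise.
#' @param gpp_noise_cv Relative s.d. of GPP noise about the WUE x ET line.
#' @param trend Secular GPP trend (fraction per year).
#' @param wue_max,wue_half_sat Water-use-efficiency map
#'   `WUE = wue_max * AI / (AI + wue_half_sat)` (g C per mm), saturating
#'   along the aridity gradient.
#' @param wue_decline_ai,wue_decline_power Soft decline of WUE as the
#'   aridity index approaches 1 (carbon and water fluxes decouple when
#'   water stops limiting production): the saturating curve is divided by
#'   `1 + (AI / wue_decline_ai)^wue_decline_power`.
#' @param sw_sens_humid GPP sensitivity to relative radiation anomalies in
#'   humid (AI >= 1) cells.
#' @param p_sens_humid Residual GPP sensitivity to precipitation
#'   anomalies in humid cells (weak by construction).
#' @param sw_sens_dry Direct radiation coefficient in water-limited cells
#'   (small and negative: bright years are drought years).
#' @param sw_noise_cv Relative s.d. of radiation noise unrelated to
#'   cloudiness.
#' @param cloud_coef Radiation-precipitation anticorrelation strength.
#' @param sif_noise_sd Additive SIF noise s.d. (mW m-2 sr-1 nm-1).
#' @param sif_k_range Range of the per-biome SIF/GPP slope
#'   (mW m-2 sr-1 nm-1 per g C m-2 month-1).
#' @param model_bias Length-`n_models` multiplicative biases (recycled).
#' @param model_noise_base,model_noise_step Per-model relative s.d. of
#'   transient (cell-month) noise,
#'   `model_noise_base + model_noise_step * (m - 1)`.
#' @param model_struct_base,model_struct_ratio Per-model relative s.d. of
#'   the persistent spatial error field,
#'   `model_struct_base * model_struct_ratio^(m - 1)`. This structural
#'   error does not average out over the training window and is what
#'   separates model scores; together with the transient noise it makes
#'   the m-th model strictly worse than the (m-1)-th, fixing the truth
#'   quality ranking.
#' @param n_et_products Number of synthetic ET products.
#' @return A `world_config` list.
#' @export
world_config <- function(nlat = 24, nlon = 36,
                         years = 2000:2011,
                         training_years = 2007:2011,
                         n_biomes = 4, n_models = 14, seed = 42,
                         ai_range = c(0.02, 2.5),
                         pet_range = c(700, 1800),
                         n_range = c(0.5, 2),
                         cv_p_coef = 0.12, cv_p_exponent = 0.7,
                         cv_p_max = 0.45,
                         cv_pet = 0.03, et_noise_cv = 0.02,
                         gpp_noise_cv = 0.03, trend = 0.005,
                         wue_max = 2.5, wue_half_sat = 0.08,
                         wue_decline_ai = 0.9, wue_decline_power = 6,
                         sw_sens_humid = 0.8, p_sens_humid = 0.1,
                         sw_sens_dry = -0.3, cloud_coef = 0.1,
                         sw_noise_cv = 0.015,
                         sif_noise_sd = 0.25,
                         sif_k_range = c(0.008, 0.018),
                         model_bias = NULL,
                         model_noise_base = 0.04,
                         model_noise_step = 0.03,
                         model_struct_base = 0.03,
                         model_struct_ratio = 1.3,
                         n_et_products = 3) {
  if (n_models < 2) validation_error("need at least 2 models")
  if (n_biomes < 1) validation_error("need at least 1 biome")
  if (any(n_range < 0.5 - 1e-12) || any(n_range > 2 + 1e-12)) {
    validation_error("Budyko exponent range must lie within [0.5, 2]")
  }
  if (any(pet_range <= 0) || any(ai_range <= 0)) {
    validation_error("PET and aridity ranges must be positive")
  }
  if (cv_p_coef < 0 || cv_pet < 0) validation_error("CVs must be >= 0")
  if (is.null(model_bias)) {
    model_bias <- 1 + 0.2 * sin(seq_len(n_models))
  }
  structure(as.list(environment()), class = "world_config")
}

#' Sample an annual precipitation series
#'
#' `P_t = mean * (1 + eps_t)` with `eps_t` iid Gaussian of s.d. `cv`,
#' truncated from below at 5\% of the mean so precipitation stays
#' positive.
#'
#' @param mean Mean annual precipitation (mm), positive.
#' @param cv Coefficient of variation, non-negative.
#' @param years Number of years to draw.
#' @param seed Integer seed.
#' @return Numeric vector of length `years`.
#' @export
sample_precipitation_series <- function(mean, cv, years, seed) {
  if (mean <= 0) validation_error("mean must be positive")
  if (cv < 0) validation_error("cv must be non-negative")
  with_seed(seed, {
    pmax(mean * (1 + stats::rnorm(years, 0, cv)), 0.05 * mean)
  })
}

# Per-biome fixed seasonal shapes (12 multiplicative weights, mean 1).
seasonal_shapes <- function(J) {
  amps <- 0.3 + 0.5 * (seq_len(J) - 1) / max(J - 1, 1)
  peaks <- 1 + ((seq_len(J) * 5) %% 12)
  t(vapply(seq_len(J), function(j) {
    s <- 1 + amps[j] * cos(2 * pi * (1:12 - peaks[j]) / 12)
    s / mean(s)
  }, numeric(12)))
}

#' Build the synthetic world
#'
#' Deterministic for a fixed seed. See [world_config()] for the
#' generative contract; the returned object carries every truth map
#' needed for parameter-recovery tests.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list: climate and flux cubes (`p`, `pet`,
#'   `t`, `sw`, `et` annual; `gpp` annual truth; `gpp_monthly`, `sif`
#'   monthly), `et_products` (list of annual cubes), `models` (named list
#'   of monthly model GPP cubes), `biomes`, truth fields `ai`, `n`,
#'   `wue`, the `model_table`, and the `config`.
#' @export
build_world <- function(config = world_config()) {
  cfg <- config
  grid <- grid_spec(seq(-58.75, 58.75, length.out = cfg$nlat),
                    seq(-177.5, 177.5, length.out = cfg$nlon))
  nlat <- cfg$nlat; nlon <- cfg$nlon
  years <- cfg$years
  ny <- length(years)
  t0 <- mean(years)

  # --- mean climate: aridity gradient along longitude, PET along latitude
  ai_lon <- exp(seq(log(cfg$ai_range[1]), log(cfg$ai_range[2]),
                    length.out = nlon))
  lat_factor <- exp(seq(-0.15, 0.15, length.out = nlat))
  ai <- outer(lat_factor, ai_lon)
  coslat <- cos(grid$lat * pi / 180)
  pet_mean <- matrix(cfg$pet_range[1] +
                       diff(cfg$pet_range) * coslat^2, nlat, nlon)
  p_mean <- ai * pet_mean
  t_mean <- matrix(25 - 0.4 * abs(grid$lat), nlat, nlon)
  sw_mean <- matrix(150 + 100 * coslat, nlat, nlon)

  n_map <- with_seed(stream_seed(cfg$seed, "budyko_n"), {
    matrix(stats::runif(nlat * nlon, cfg$n_range[1], cfg$n_range[2]),
           nlat, nlon)
  })
  # wue_sat: productivity per unit water along the gradient.
  # wue: the GPP-ET coupling slope, additionally declining as AI -> 1
  # where carbon and water fluxes decouple; this is the beta truth.
  wue_sat <- cfg$wue_max * ai / (ai + cfg$wue_half_sat)
  wue <- wue_sat / (1 + (ai / cfg$wue_decline_ai)^cfg$wue_decline_power)
  cv_p <- pmin(cfg$cv_p_coef * ai^(-cfg$cv_p_exponent), cfg$cv_p_max)

  # --- annual anomalies (independent across cells and years)
  draw <- function(name, sd = 1) {
    with_seed(stream_seed(cfg$seed, name), {
      array(stats::rnorm(ny * nlat * nlon, 0, sd), c(ny, nlat, nlon))
    })
  }
  eps_p <- draw("eps_p") * rep(cv_p, each = ny)
  p_ann <- pmax(rep(p_mean, each = ny) * (1 + eps_p),
                0.05 * rep(p_mean, each = ny))
  pet_ann <- rep(pet_mean, each = ny) * (1 + draw("eps_pet", cfg$cv_pet))
  sw_rel <- -cfg$cloud_coef * eps_p + draw("eps_sw", cfg$sw_noise_cv)
  sw_ann <- rep(sw_mean, each = ny) * (1 + sw_rel)
  t_ann <- rep(t_mean, each = ny) + 8 * sw_rel + draw("eps_t", 0.3)

  et_clean <- array(budyko_et(p_ann, pet_ann, rep(n_map, each = ny)),
                    c(ny, nlat, nlon))
  et_mean_map <- apply(et_clean, c(2, 3), mean)
  et_ann <- pmax(et_clean +
                   draw("eps_et") * cfg$et_noise_cv * rep(et_mean_map,
                                                          each = ny),
                 0)

  # --- truth GPP: water-limited (AI < 1) vs radiation-driven humid cells
  dt <- years - t0
  trend_fac <- 1 + cfg$trend * dt
  water_limited <- ai < 1
  gpp_wl <- rep(wue, each = ny) * et_ann *
    rep(trend_fac, nlat * nlon) * (1 + cfg$sw_sens_dry * sw_rel)
  gpp_mean_wl <- rep(wue * et_mean_map, each = ny)
  gpp_hum_mean <- wue_sat * et_mean_map
  gpp_hum <- rep(gpp_hum_mean, each = ny) *
    (rep(trend_fac, nlat * nlon) + cfg$sw_sens_humid * sw_rel +
       cfg$p_sens_humid * eps_p)
  wl_arr <- rep(water_limited, each = ny)
  gpp_ann <- ifelse(wl_arr, gpp_wl, gpp_hum)
  gpp_noise_scale <- ifelse(wl_arr, gpp_mean_wl,
                            rep(gpp_hum_mean, each = ny))
  gpp_ann <- pmax(gpp_ann + draw("eps_gpp") * cfg$gpp_noise_cv *
                    gpp_noise_scale, 0)
  gpp_ann <- array(gpp_ann, c(ny, nlat, nlon))

  # --- biomes: smooth mixtures along the log-aridity gradient
  J <- cfg$n_biomes
  centers <- exp(seq(log(0.05), log(2), length.out = J))
  kern <- array(NA_real_, c(J, nlat, nlon))
  for (j in seq_len(J)) {
    kern[j, , ] <- exp(-(log(ai) - log(centers[j]))^2 / 0.8)
  }
  ksum <- apply(kern, c(2, 3), sum)
  fractions <- array(NA_real_, c(J, nlat, nlon))
  for (j in seq_len(J)) fractions[j, , ] <- 0.95 * kern[j, , ] / ksum
  labels <- paste0("biome", seq_len(J))
  biomes <- biome_fractions(fractions, labels, grid)

  # --- monthly truth GPP and SIF
  shapes <- seasonal_shapes(J)  # [J, 12]
  cell_shape <- array(0, c(12, nlat, nlon))
  for (j in seq_len(J)) {
    cell_shape <- cell_shape + outer(shapes[j, ], fractions[j, , ] / 0.95)
  }
  months <- as.vector(t(outer(years * 100, 1:12, `+`)))
  nm <- length(months)
  gpp_month <- array(NA_real_, c(nm, nlat, nlon))
  for (k in seq_len(ny)) {
    idx <- (k - 1) * 12 + 1:12
    gpp_month[idx, , ] <- rep(gpp_ann[k, , ] / 12, each = 12) * cell_shape
  }
  k_biome <- seq(cfg$sif_k_range[1], cfg$sif_k_range[2], length.out = J)
  k_cell <- apply(fractions * k_biome, c(2, 3), sum) /
    apply(fractions, c(2, 3), sum)
  sif_noise <- with_seed(stream_seed(cfg$seed, "sif"), {
    array(stats::rnorm(nm * nlat * nlon, 0, cfg$sif_noise_sd),
          c(nm, nlat, nlon))
  })
  sif_month <- rep(k_cell, each = nm) * gpp_month + sif_noise

  # --- model ensemble: bias x (1 + persistent spatial error) x truth
  #     + transient noise; quality ranking fixed by the error ladder
  M <- cfg$n_models
  bias <- rep_len(cfg$model_bias, M)
  noise_frac <- cfg$model_noise_base + cfg$model_noise_step * (seq_len(M) - 1)
  struct_frac <- cfg$model_struct_base * cfg$model_struct_ratio^(seq_len(M) - 1)
  gpp_month_clim <- apply(gpp_month, c(2, 3), mean)
  model_names <- sprintf("model%02d", seq_len(M))
  models <- vector("list", M)
  names(models) <- model_names
  for (m in seq_len(M)) {
    stream <- stream_seed(cfg$seed, paste0("model_", model_names[m]))
    delta <- with_seed(stream, {
      matrix(stats::rnorm(nlat * nlon, 0, struct_frac[m]), nlat, nlon)
    })
    nz <- with_seed(stream + 1L, {
      array(stats::rnorm(nm * nlat * nlon), c(nm, nlat, nlon))
    })
    vals <- pmax(bias[m] * rep(pmax(1 + delta, 0.05), each = nm) * gpp_month +
                   nz * noise_frac[m] * rep(gpp_month_clim, each = nm), 0)
    models[[m]] <- gridded_cube(vals, months, grid,
                                units = "g C m-2 month-1", freq = "monthly")
  }
  model_table <- data.frame(model = model_names, bias = bias,
                            noise_frac = noise_frac,
                            struct_frac = struct_frac,
                            quality_rank = seq_len(M))

  # --- synthetic ET products: truth + product-specific noise
  et_products <- lapply(seq_len(cfg$n_et_products), function(k) {
    nz <- with_seed(stream_seed(cfg$seed, paste0("et_product_", k)), {
      array(stats::rnorm(ny * nlat * nlon), c(ny, nlat, nlon))
    })
    gridded_cube(pmax(et_ann + nz * 0.02 * k * rep(et_mean_map, each = ny),
                      0),
                 years, grid, units = "mm yr-1", freq = "annual")
  })
  names(et_products) <- sprintf("et_product%02d", seq_len(cfg$n_et_products))

  cube <- function(v, units, freq = "annual", time = years) {
    gridded_cube(array(v, c(length(time), nlat, nlon)), time, grid,
                 units = units, freq = freq)
  }
  field <- function(v, units = "") grid_field(v, grid, units)
  structure(list(
    grid = grid,
    p = cube(p_ann, "mm yr-1"),
    pet = cube(pet_ann, "mm yr-1"),
    t = cube(t_ann, "degC"),
    sw = cube(sw_ann, "W m-2"),
    et = cube(et_ann, "mm yr-1"),
    gpp = cube(gpp_ann, "g C m-2 yr-1"),
    gpp_monthly = cube(gpp_month, "g C m-2 month-1", "monthly", months),
    sif = cube(sif_month, "mW m-2 sr-1 nm-1", "monthly", months),
    et_products = et_products,
    models = models,
    biomes = biomes,
    ai = field(ai),
    n = field(n_map),
    wue = field(wue, "g C mm-1"),
    cv_p = field(cv_p),
    p_mean = field(p_mean, "mm yr-1"),
    pet_mean = field(pet_mean, "mm yr-1"),
    water_limited = field(water_limited + 0),
    model_table = model_table,
    config = cfg
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d grid, years %d-%d, %d models, %d biomes\n",
    x$grid$nlat, x$grid$nlon, min(x$config$years), max(x$config$years),
    x$config$n_models, x$config$n_biomes))
  invisible(x)
}

#' Truth table of the synthetic world
#'
#' Per-cell truth parameters (aridity index, Budyko exponent, WUE) and
#' the per-model bias/noise specification. All distributional choices in
#' the generator are stand-ins for observational structure, not fitted
#' quantities; this table is the reference for recovery tests.
#'
#' @param world A [build_world()] result.
#' @return List of two data frames, `cells` and `models`.
#' @export
world_truth_table <- function(world) {
  grid <- world$grid
  idx <- expand.grid(ilat = seq_len(grid$nlat), ilon = seq_len(grid$nlon))
  cells <- data.frame(
    lat = grid$lat[idx$ilat], lon = grid$lon[idx$ilon],
    ai = as.vector(world$ai$values),
    n = as.vector(world$n$values),
    wue = as.vector(world$wue$values),
    water_limited = as.vector(world$water_limited$values) > 0
  )
  list(cells = cells, models = world$model_table)
}
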