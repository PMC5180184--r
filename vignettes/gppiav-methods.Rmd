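---
title: "Methods: a SIF-weighted GPP ensemble, aridity-resolved IAV, and the Budyko chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a SIF-weighted GPP ensemble, aridity-resolved IAV, and the Budyko chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Terrestrial gross primary production (GPP) carries a rising trend with
large year-to-year fluctuations superimposed. The fluctuations are not
spatially uniform: semi-arid ecosystems — a modest fraction of the land
surface — dominate the detrended interannual variability (IAV) of the
global flux. `gppiav` implements a complete chain for dissecting why:

> σ_GPP ≈ β · σ_ET ≈ β · (∂ET/∂P) · σ_P

In water-limited climates GPP and evapotranspiration (ET) are tightly
coupled through stomata (slope β, an ecosystem water-use-efficiency
proxy), ET is supply-driven (Budyko sensitivity ∂ET/∂P near 1), and
relative precipitation variability is high. Each factor is estimated by
a separate module, so the chain can be tested link by link.

## The ensemble model and its assumptions

No direct global GPP measurement exists; models disagree, and an
unweighted model average is vulnerable to outliers. Solar-induced
chlorophyll fluorescence (SIF) is an independent satellite proxy that is
approximately proportional to GPP *within a biome*, though with
retrieval noise (0.1–0.4 mW m⁻² sr⁻¹ nm⁻¹) that is large relative to
monthly signal levels (0–4 mW m⁻² sr⁻¹ nm⁻¹). Averaging — over the
training years for the spatial mode, over cells within a biome for the
temporal mode — suppresses that noise before correlating.

The weighting scheme assumes only that a model whose GPP field
correlates better with SIF inside each biome is more trustworthy; it
never rescales model amplitudes toward SIF (correlation is
affine-invariant), so the ensemble remains a convex combination of the
models. Key choices, following the stated design contract:

* **Spatial mode trains on the mean annual map** over the training
  window (default 2007–2011, the overlap of the emulated products),
  rather than pooling per-year maps; per-year pooling would weight
  interannual noise into a score meant to capture spatial
  representativeness. Weights learned there are applied to the full
  2000–2011 window. Only the spatial-mode ensemble feeds downstream
  analysis; temporal-mode scores are computed and reported.
* **Fractional biome membership**: a cell contributes to every biome in
  proportion to its cover fraction (cell weight = area × fraction), with
  a dominant-type option. Biomes with fewer than 3 effective cells are
  flagged and excluded, with the area fractions renormalised.
* **Negative scores are floored at zero** before the power weighting
  W_i ∝ max(score_i, 0)^γ. Odd γ would otherwise admit negative weights
  and even γ would reward anti-correlated models; a model anti-correlated
  with the proxy should get no weight at all.
* **Default γ = 2**, with {1, 2, 4} swept by the pipeline; larger γ
  concentrates weight on the top-scoring model (γ → ∞ selects it).

## Trend, anomalies and contributions

Per-cell ordinary least squares against calendar year splits each annual
series into trend and residual anomalies. IAV is the **population**
(divide-by-N) standard deviation — of the residuals for the contribution
analysis, of the raw annual values for maps — because the
divide-by-N convention makes the variance decompositions below exact
identities; a sample-s.d. flag is available.

Class contributions to the global detrended variance use the projection
form f_j = Σ_t x_jt X_t / Σ_t X_t², where x_jt are area-integrated class
anomaly series and X_t their sum. This form is exactly additive
(Σ f_j = 1, merging classes adds their contributions) and reduces to
variance shares for uncorrelated regions; the plain variance-share
alternative is available behind a flag since published headline
percentages could be either. Class series are integrated first and
detrended as series (per-cell detrending first is offered as an option;
the two differ only through trend-map nonuniformity). Trend
contributions are class slopes over the global slope, which sum to one
by linearity of OLS.

## Attribution

Partial correlations use the residual method — correlate the OLS
residuals of GPP and of the driver on the remaining drivers — which is
equivalent to the precision-matrix form, extends to any number of
controls, and is tested against the three-variable closed form at 1e-10.
The two-sided p-value uses t with N − 2 − k degrees of freedom; its
type-I error at α = 0.05 is verified to be 0.05 ± 0.01 over 10⁴ null
cells at N = 12 years. Per-cell tests are uncorrected
(a Benjamini–Hochberg option exists but is off by default) to match how
"fraction of area significant" figures are conventionally quoted.
Partial correlations default to raw annual series (the convention when
"annual GPP" is attributed), with a detrended option; the coupling slope
β always uses detrended anomalies, matching the σ_GPP = β·σ_ET context.
β = r·σ_GPP/σ_ET holds identically and links the slope maps to the
correlation maps.

## The Budyko module

The analytical curve ET = P·PET/(Pⁿ + PETⁿ)^(1/n) (the one-parameter
solution of the Budyko hypothesis; Fu's closely related
ET = P(1 + x − (1 + xⁿ)^(1/n)) form is available behind a switch for
sensitivity analysis) gives closed-form sensitivities

∂ET/∂P = PETⁿ⁺¹/(Pⁿ + PETⁿ)^((n+1)/n),  ∂ET/∂PET symmetric.

ET is degree-1 homogeneous, so P·∂ET/∂P + PET·∂ET/∂PET = ET (checked to
1e-8). σ_ET is propagated to first order (delta method) with P and PET
independent, returning the two components separately so the claim that
the PET contribution is negligible is *checked*, not assumed. The
landscape exponent defaults to the stated global range [0.5, 2];
envelope curves use n ∈ {0.5, 1, 2}. `fit_n` inverts the curve by
bracketed 1-D least squares on n ∈ [0.05, 20], flagging edge
convergence and under-determined (< 3 point) fits.

### Numerical choices

* ET and its derivatives factor out max(P, PET) before exponentiation,
  so aridity ratios of 1e±6 are evaluated without overflow.
* Truncation at finite aridity: 1 − ∂ET/∂P = 1 − (1 + AIⁿ)^(−(n+1)/n) ≈
  ((n+1)/n)·AIⁿ. At AI = 1e-6 this is ~2e-6 for n = 1 but **3e-3 for
  n = 0.5**: the slow n = 0.5 tail cannot meet a 1e-4 tolerance at
  AI = 1e-6, and the corresponding acceptance assertion is deliberately
  left failing rather than evaluated at a smaller AI than stated.
* Aridity classes use half-open boundaries [lower, upper) at
  0.05 / 0.2 / 0.5 / 0.65 (UNEP convention; configurable), so AI = 0.65
  is humid and 0.649 dry sub-humid; drylands are AI < 0.65.
* Units are declared strings validated against an alias table, never
  silently converted; area weights are cos(latitude) of cell centres
  normalised to sum 1 (error < 0.01% versus exact spherical bands at
  0.5°); the shared land mask is the intersection of all inputs' valid
  cells.
* Gridded files are a self-describing JSON text container with CF-style
  metadata (coordinates, units, long_name, `_FillValue`): the supported
  toolchain has no NetCDF bindings, and the round-trip, missing-variable
  and masking contracts are preserved and tested.

## What the synthetic world emulates — and what it does not

The generator builds a planet whose *statistical structure* matches the
assumptions above, with all truth maps retained for recovery tests:

* An aridity-index gradient (log-spaced 0.02–2.5 along longitude,
  modulated ±15% across latitude) covering all five classes; PET
  700–1800 mm yr⁻¹ by latitude; P̄ = AI·PET̄.
* Annual precipitation P_t = P̄(1 + ε_t), ε_t Gaussian, independent
  across years and cells, truncated at 5% of the mean. Its coefficient
  of variation declines with aridity index as 0.12·AI^(−0.7) capped at
  0.45 — roughly 0.3–0.45 in hyper-arid, ~0.12 at AI = 1, under 0.1 in
  the wettest cells, the observed shape of annual rainfall variability.
  PET varies with CV 0.03.
* ET_t follows the Budyko curve with a known per-cell n ~ U(0.5, 2) plus
  2% noise, so ET/P respects the supply bound climatologically.
* Water-limited cells (AI < 1): GPP_t = WUE·ET_t·(1 + trend·Δt) + 3%
  noise. The coupling slope WUE = 2.5·AI/(AI + 0.08), softly divided by
  1 + (AI/0.9)⁶ so the slope declines as AI approaches 1 — carbon and
  water fluxes decouple when water stops limiting production, while
  productivity per unit water (which sets humid mean GPP) does not
  decline. Humid cells (AI ≥ 1) are radiation-driven with weak residual
  precipitation dependence and ~3% total relative IAV (humid GPP is
  climate-stable); radiation anomalies anti-correlate with precipitation
  through cloudiness, which is what makes GPP–radiation partial
  correlations negative where precipitation dominates.
* SIF_t = k_biome·GPP_t + Gaussian noise of 0.25 mW m⁻² sr⁻¹ nm⁻¹ per
  cell-month (mid retrieval-uncertainty scale), k per biome in
  0.008–0.018 (mW m⁻² sr⁻¹ nm⁻¹)/(g C m⁻² month⁻¹). Monthly fields come
  from fixed per-biome seasonal shapes, so annual sums are exact.
* Model m GPP = b_m·(1 + δ_m(cell))·truth + transient cell-month noise.
  The persistent spatial error field δ_m (s.d. 0.03·1.3^(m−1)) is
  essential: purely transient noise averages out of a 5-year training
  map and cannot separate scores beyond sampling error, whereas a
  persistent structural bias pattern — the realistic signature of
  inter-model spread — yields a score ranking that recovers the truth
  quality ranking exactly (tested across seeds). Transient noise s.d. is
  0.04 + 0.03·(m−1) of the cell's climatological mean.
* One master seed; every random field draws from its own (seed, name)
  stream, so adding a field never perturbs the others, and adding models
  never changes the climate.

Not emulated: spatially correlated weather or noise, ENSO
teleconnections, autocorrelated annual anomalies, vegetation dynamics,
snow/storage terms in the water balance, retrieval artefacts such as the
South Atlantic Anomaly. A green test therefore establishes that the
*estimators* are correct and well calibrated under the stated generative
structure, not that the headline numbers of any observational analysis
are reproduced; the published global totals and percentage shares depend
on 14 external model products and are out of desk-scale reach by
construction.

## Known limitations

* The humid/water-limited regime switch at AI = 1 is binary; real
  ecosystems transition smoothly, so cells just below 1 mix behaviours
  only through the declining coupling slope.
* First-order σ_ET propagation ignores curvature of the Budyko surface;
  the Monte-Carlo check bounds the error at ~5% for CV_P = 0.1 at
  AI = 0.3 but it grows with CV_P.
* Leave-one-out stability compares s.d. across replicates only; it does
  not bootstrap the training window.
* The JSON grid container stores doubles at full printed precision;
  round-trips are exact to ~1e-15 relative, not bit-exact.
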