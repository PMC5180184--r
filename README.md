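# gppiav

Tools for analysing what controls the **interannual variability (IAV) of
terrestrial gross primary production (GPP)** — the year-to-year swings of
the largest carbon flux on land — and why those swings concentrate in
semi-arid ecosystems.

## Who this is for

Carbon-cycle and land-surface researchers who work with gridded
multi-model GPP fields, satellite solar-induced chlorophyll fluorescence
(SIF), and gridded climate/water-flux products, and who want a tested,
reproducible implementation of:

1. **SIF-weighted model ensembling.** Per model *i* and biome *j*, the
   Pearson correlation r_ij between the model's GPP and SIF is computed
   across cells within the biome (spatial mode, on training-window mean
   annual maps) or across within-biome monthly means (temporal mode).
   Scores are biome-area-weighted averages, score_i = Σ_j a_j r_ij, and
   ensemble weights are order-γ powers,
   W_i = max(score_i, 0)^γ / Σ_k max(score_k, 0)^γ, applied as
   GPP_ens = Σ_i W_i GPP_i. A leave-one-model-out comparison quantifies
   the stability gain over unweighted averaging.
2. **Trend / IAV decomposition.** Per-cell OLS against calendar year
   splits annual GPP into a secular trend and detrended anomalies;
   aridity classes (UNEP boundaries 0.05 / 0.2 / 0.5 / 0.65 on the
   aridity index AI = P/PET) receive exactly additive contributions to
   the global detrended variance, f_j = Σ_t x_jt X_t / Σ_t X_t², and to
   the global trend (class slope / global slope).
3. **Climate and coupling attribution.** Per-cell partial correlations
   of annual GPP with precipitation, temperature and shortwave radiation
   (each controlling the other two); the GPP–ET coupling slope β (an
   ecosystem water-use-efficiency proxy where water-limited); and the
   decomposition σ_GPP = β·σ_ET.
4. **The Budyko framework.** The analytical curve
   ET = P·PET / (Pⁿ + PETⁿ)^(1/n) with landscape exponent n ∈ [0.5, 2],
   its closed-form sensitivity ∂ET/∂P = PETⁿ⁺¹/(Pⁿ + PETⁿ)^((n+1)/n)
   (1 in hyper-arid, 0 in extremely humid climates), and first-order
   propagation σ_ET ≈ |∂ET/∂P|·σ_P, closing the chain
   σ_GPP ≈ β·(∂ET/∂P)·σ_P.

A seeded **synthetic world** with known ground truth (per-cell n, WUE,
aridity; per-model bias/noise quality ranking) stands in for the real
gridded products so every stage is verifiable at desk scale.

## Worked example

```r
library(gppiav)

w  <- build_world(world_config(seed = 42))      # the stated default world
sc <- ensemble_scores(w$models, w$sif, w$biomes,
                      training_years = 2007:2011)
round(head(sc$scores, 4), 4)
#> model01 model02 model03 model04
#>  0.9733  0.9718  0.9705  0.9660
cor(rank(-sc$scores), w$model_table$quality_rank, method = "spearman")
#> [1] 1                                  # scores recover the truth ranking

ens <- weighted_ensemble(lapply(w$models, to_annual, "sum"),
                         ensemble_weights(sc$scores, gamma = 2))
```

Aridity classification and contribution analysis on the same world:

```r
cls <- classify_aridity(w$ai)
ci  <- regional_contribution_iav(decompose_trend(w$gpp)$anomalies, cls)
round(ci$fractions, 3)
#>    hyper-arid          arid     semi-arid dry sub-humid         humid
#>         0.062         0.011         0.468         0.200         0.258
```

Semi-arid cells (AI 0.2–0.5) carry the largest share (47%) of global
detrended GPP variance, and the binned IAV-versus-aridity curve of the
weighted ensemble peaks at AI ≈ 0.35 — the headline pattern the
pipeline is built to dissect: both the coupling slope β and
precipitation-driven ET variability peak in that band.

Full pipeline from one config (writes scores, weights, ensembles,
contributions, binned curves and a manifest):

```r
mf <- run_pipeline(pipeline_config(out_dir = "run1", seed = 42))
summarize_run("run1/manifest.json")$global_gpp
```

or from a shell: `inst/scripts/gppiav run --out run1 --seed 42`.

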