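# riverTe

Thermal exposure risk modelling for river fish life stages.

`riverTe` asks how often, where, and in which months a regulated river's
water temperature leaves the range each early life stage of white sturgeon
(*Acipenser transmontanus*) tolerates — and how that changes under warming
scenarios. It bundles four pieces into one tested pipeline:

1. **A semi-distributed daily hydrological–thermal model.** Square grid
   cells linked in a drainage tree, each subdivided into up to four
   hydrological response units with three interconnected reservoirs
   (degree-day snow, capacity-spill soil, ground, lake), linear channel
   routing, and an equilibrium-temperature water-temperature module with
   discharge-weighted mixing and a cold dam-release boundary. The daily loop
   is compiled (Rcpp) and verified against a naive pure-R reference to 1e-10.
2. **Two-step calibration.** Hydrology is fitted to observed streamflow,
   then the thermal module to observed water temperature, with a
   covariance matrix adaptation evolution strategy (CMA-ES) minimising a
   gap-aware RMSE (or −NSE) inside parameter boxes. `calibrate_two_step()`
   returns a classed fit with `coef`, `summary`, `predict`, `residuals`,
   `simulate` and `plot` methods.
3. **The thermal exposure index T_e.** Each day's temperature interval
   [T_a, T_b] maps to an ordinal category per life stage:

   | T_e | meaning | embryo / larvae18 / juvenile | yolk-sac / larvae20 |
   |-----|-----------------------|--------------|--------------|
   | 0 | below optimal | < 14 °C | < 14 °C |
   | 1 | optimal range T_optR | 14–18 °C | 14–20 °C |
   | 2 | sub-optimal range ST_optR | > 18 °C | > 20 °C |
   | 3 | critical range CT_LR | user-supplied only | user-supplied only |

   Intervals inside one band take that band's category; straddling intervals
   use a conservative max-band rule by default (a midpoint mode is
   available). Categories are averaged numerically over days, months,
   ensemble members, decades (1980s/2050s/2090s) and critical-habitat
   polygons, within each stage's presence window (embryo 15 May–24 Jun,
   yolk-sac 24 May–7 Jul, feeding larvae 20 Jun–31 Jul, juvenile
   1 May–31 Oct).
4. **Synthetic-data generators** for everything upstream: watershed,
   seasonal AR(1) meteorology, pseudo-GCM ensembles for SSP2-4.5 and
   SSP5-8.5, noisy gauge observations with gaps, and habitat masks — all
   pure functions of their seeds, so the whole study runs offline with known
   truth.

A configuration-driven orchestrator, `run_pipeline()`, chains
generate → simulate → classify → aggregate → report and writes CSV/GeoJSON
artifacts plus a JSON manifest; `stmp_controller()` explores proportional
cold-water dam releases against a 20 °C threshold in the 20 July–20 August
management window.

## Worked example

Calibrate against five years of noisy synthetic gauge data, then classify
embryo exposure:

```r
library(riverTe)
grid    <- make_watershed(12, seed = 7)
forcing <- make_meteorology(grid, 1999:2004, seed = 2)
truth_h <- hydro_params(degree_day_factor = 4, routing_coeff = 0.5)
truth_t <- thermal_params(exchange_coeff = 0.3)
obs <- make_observations(grid, forcing, truth_h, truth_t,
                         stations = grid$outlet_id,
                         noise_sd = c(flow = 0.01, temp = 0.5), seed = 3)
fit <- calibrate_two_step(grid, forcing, obs, obs,
  hydro_config = calibration_config(list(degree_day_factor = c(0.5, 8),
                                         routing_coeff = c(0.1, 0.95)),
                                    max_evaluations = 800, seed = 11),
  thermal_config = calibration_config(list(exchange_coeff = c(0.05, 0.9),
                                           eq_temp_offset = c(-3, 5)),
                                      max_evaluations = 800, seed = 12))
summary(fit)
#> Two-step hydrothermal model fit
#>
#> Estimated parameters:
#> hydro.degree_day_factor     hydro.routing_coeff  thermal.exchange_coeff
#>                 4.08690                 0.48365                 0.45044
#>  thermal.eq_temp_offset
#>                 0.46948
#>
#> Objectives: flow 0.009972 (348 evals), water temperature 0.50558 (258 evals)
#>
#> Per-station diagnostics:
#>  station_cell   variable n_obs        rmse       nse
#>             1       flow  1827 0.009972001 0.8908016
#>             1 water_temp  1827 0.505582525 0.9945337
#>
#> Water-balance drift of the fitted run: 3.04e-11 mm
```

The injected truth was `degree_day_factor = 4`, `routing_coeff = 0.5`, and
the temperature RMSE (0.506 °C) sits on the injected 0.5 °C noise floor —
the fit has extracted everything the noisy gauges contain. Exposure
classification then runs on the fitted model's predictions:

```r
cube <- predict(fit)
emb  <- thermal_thresholds("embryo")
head(aggregate_te(list(daily_te(cube, emb)), life_stage = "embryo"), 2)
#>   scope life_stage month period scenario    mean_te      sd_te n
#> 1     1     embryo     5   <NA>     <NA> 0.01176471 0.02630668 5
#> 2     1     embryo     6   <NA>     <NA> 0.41666667 0.22821773 5

classify_interval(10, 12, emb)   # a 10-12 degC day is below optimal
#> [1] 0
percent_change(19.7, 17)         # warming expressed against a baseline
#> [1] 16
```

Mean embryo exposure near 0 in May (river below 14 °C most days) rising
toward the optimal band in June is exactly the seasonal pattern the index is
built to expose. The full synthetic study — scenarios × periods × life
stages, habitat tables, monthly temperature statistics — is one call:

```r
run_pipeline(demo_config(out_dir = "demo_run", seed = 1))
```

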