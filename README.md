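# microkrige

Fine-scale mapping of pedestrian-level particulate matter (PM2.5 / PM10)
from mobile walking transects, for exposure assessment in compact urban
districts.

A walking survey — an optical particle counter, weather sensor and GPS
logger carried at 0.8 m/s with 1 s sampling, forward and backward along a
route — yields a dense point cloud of raw concentrations. `microkrige`
turns it into a concentration surface:

1. **Preprocess** — correct the optical readings for hygroscopic growth,
   `CF(RH) = 1 + 0.25·RH²/(1−RH)`, corrected = raw / CF; merge the two
   passes by greedy spatial clustering (2 m radius).
2. **Covariates** — sky-view factor (SVF), frontal-area index (FAI) and
   road-area ratio (RDA) in a 50 m buffer, from building footprints with
   heights and road polygons.
3. **Variogram** — empirical semivariogram
   `γ(d) = (1/2n(d)) Σ [Z(sᵢ) − Z(sⱼ)]²`, fitted by Cressie-weighted least
   squares to the stable family
   `γ(d) = c₀ + c·[1 − exp(−(3d/a)^ω)]` (exponential ω = 1, Gaussian ω = 2)
   or the spherical model; `major_range()` gives the 95 %-of-sill distance.
4. **Interpolate** — the 13 configurations: local polynomial interpolation
   (LPI, six kernels, e.g. `K(r) = e^(−3r/h)`), ordinary kriging (OK),
   ordinary cokriging with 1–3 covariates (OCK), and kernel interpolation
   with building barriers (KIB, shortest-path distances around footprints).
5. **Validate** — leave-one-out RMSE (Eq. `√(1/n Σ (PM′ᵢ − PMᵢ)²)`) and
   2-fold cross-validated R² (squared Pearson correlation of pooled
   out-of-fold predictions), per method and variable, with summaries by
   algorithm and by covariate.

Because mobile-campaign datasets of this kind are rarely shared, a
first-class synthetic module (`make_street_grid()`, `simulate_pm_field()`,
`simulate_walk()`) generates street-grid scenes, Gaussian-random-field PM
surfaces with roadside hotspots, and noisy transects with the campaign's
stated properties (RH ≈ 85 %, 4 m GPS accuracy, stable variogram with
~25 m range).

## Worked example

```r
library(microkrige)

sc  <- synth_scenario(seed = 1)                    # scene + truth + walk
rec <- sc$records[seq(1, nrow(sc$records), by = 15), ]
cl  <- preprocess_transect(rec, merge_radius = 3)
nrow(cl)
#> [1] 311

emp <- empirical_semivariogram(as.matrix(cl[, c("x", "y")]), cl$pm25)
vg  <- fit_variogram(emp, "stable")
vg
#> <mk_vgm stable: nugget 2.356, psill 16.97, range 79.82 m, shape 0.796>
major_range(vg)   # metres of spatial dependence
#> [1] 105.645

rep <- compare_methods(cl, sc$scene, k = 2, seed = 1, kib_res = 5)
rep$by_algorithm
#>  group variable rmse_loocv r2_kfold
#>    KIB     pm10      5.183   0.4169
#>    LPI     pm10      5.032   0.4316
#>    OCK     pm10      4.020   0.5316
#>     OK     pm10      4.018   0.5316
#>    KIB     pm25      3.137   0.3990
#>    LPI     pm25      3.043   0.4167
#>    OCK     pm25      2.495   0.5069
#>     OK     pm25      2.488   0.5102
```

RMSE is in µg/m³ — here ordinary kriging predicts held-out PM2.5 samples to
about ±2.5 µg/m³ and explains ~51 % of their variance in a 2-fold split;
cokriging with building-geometry covariates is within a few thousandths of
it (covariates help only slightly at this scale), and the smoothers (LPI,
KIB) trail the kriging family. A full surface for any configuration:

```r
grid <- mk_grid_for_extent(sc$scene$extent, cell = 5)
surf <- run_method(method_config("OK"), cl, sc$scene, grid,
                   variable = "pm25", variogram = vg)
write_surface(surf, "pm25_OK.asc")                 # ESRI ASCII raster
```

The full pipeline (simulate → preprocess → covariates → variogram →
13 surfaces × 2 variables → CV report → manifest) runs from a JSON config:

```r
run_pipeline(list(seed = 1, thin = 15, merge_radius = 3, grid_cell = 10),
             out_dir = "out/")
```

or from the command line:
`Rscript -e 'microkrige::microkrige_cli()' run --config cfg.json --out out/`.

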