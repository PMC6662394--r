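# forestdyn

Analysis of repeated forest-census data from permanent plots in
subtropical mixed *Araucaria* (conifer–hardwood) forest, for forest
ecologists studying stand dynamics, functional composition and their
climate context. The package covers:

* **Allometric aboveground biomass** with growth-form-specific
  equations — angiosperms via the pantropical model
  AGB = 0.0673 (ρD²H)^0.976 (kg; ρ wood density g/cm³, D dbh cm,
  H height m), *Araucaria angustifolia* via trunk + live-branch
  polynomials, palms and tree ferns via height-only equations — with
  tiered wood-density resolution (species → genus mean → global mean).
* **Functional composition** — threshold classification of species into
  ecological groups from maximum height and wood density,
  community-weighted trait means CWM = Σaⱼtⱼ/Σaⱼ, and functional
  dispersion FDis = Σaⱼ‖xⱼ − c‖/Σaⱼ (abundance-weighted distance to the
  weighted trait-space centroid).
* **Net-change inference** — per-subplot annual rates (x₂ − x₁)/t of
  biomass, basal area, stem density, CWMs and FDis, with 5,000-replicate
  percentile-bootstrap CIs over 20 × 20 m subplots, stratified by
  management (logging) history; a change is significant when the 95% CI
  excludes zero.
* **Climate trend battery** — OLS trends on annual series with F tests,
  Durbin–Watson and ACF residual diagnostics, LOESS smoothing
  (α span, locally linear, robustness iterations), the opposite-tails
  Grubbs outlier test G = (max − min)/s, and breakpoint/decade mean
  comparisons.
* **A synthetic census generator** — an individual-based simulator of
  the full sampling design (10 × 1 ha plots, 250 subplots, 148 species,
  annual censuses 2000–2009, 9.5 cm dbh entry threshold, three logging
  histories) plus a 1901–2014 climate series, with a ground-truth event
  log so every analysis stage can be validated against known dynamics.

## Worked example

```r
library(forestdyn)

forest <- generate_forest(forest_sim_config(seed = 1))
changes <- summarize_dynamics(forest$census, forest$plots, forest$traits,
                              2000, 2009,
                              boot = bootstrap_config(seed = 1))
subset(changes, variable == "biomass")
#>   variable         stratum mean_rate ci_low ci_high n_units n_boot significant t_years
#> 1  biomass             all     0.854  0.510    1.19     250   5000        TRUE       9
#> 2  biomass        unlogged     1.112  0.721    1.49     125   5000        TRUE       9
#> 3  biomass    early_logged     0.648 -0.177    1.41      50   5000       FALSE       9
#> 4  biomass recently_logged     0.561 -0.184    1.24      75   5000       FALSE       9
```

Each row is the mean annual net change of subplot aboveground biomass
(Mg/ha/yr) over the 2000–2009 interval for one stratum, with its
percentile-bootstrap 95% CI: under this simulation's default growth and
mortality rates the pooled 250 subplots gain biomass significantly
(0.85 Mg/ha/yr), the unlogged stratum fastest, while neither logged
stratum's change is distinguishable from zero.

```r
clim <- generate_climate(climate_sim_config(seed = 1))
fit_linear_trend(clim$year, clim$tmin_annual_mean)
#> Linear trend: slope = 0.010741 +/- 0.00119 per year (F = 81.53, df = 1,112, p = 5.72e-15)
#> Durbin-Watson d = 2.044; lag-1 residual ACF = -0.029
```

The fitted warming slope recovers the generator's configured
0.0118 °C/yr within its standard error, and d ≈ 2 shows uncorrelated
residuals.

A thin command-line wrapper over the same functions is installed at
`inst/cli/forestdyn-cli.R` (subcommands `simulate`, `analyze`,
`climate`, `show-config`, driven by a YAML configuration; see
`default_run_config()`).

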