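# trawlshift

Estimation of marine fish range-shift rates from bottom-trawl survey
data, for quantitative marine ecologists working with haul-level catch
tables (DATRAS-style surveys and similar monitoring programmes).

As shelf seas warm, species are expected to move poleward, but trawl
surveys observe species only through zero-inflated catches taken with a
sampling footprint that itself moves between years. `trawlshift`
implements, end to end:

* **Curation** — standardized haul filters (depth band, season, gear,
  distance to coast) and the two-pass species retention rule: a year
  counts for a species only if it was caught in ≥ 5 trawls that year,
  and a species is analysed only with ≥ 10 such years (both
  configurable).
* **Geographic shift rates** — annual biomass-weighted centroid latitude
  `lat_c = Σ bᵢ·latᵢ / Σ bᵢ` per species-year, modelled as
  `lat_c ~ s(depth_c) + β·year + γ₁·survey_mean_lat + γ₂·survey_median_lat`
  (penalized regression spline, basis dimension 4). The survey-latitude
  covariates correct for footprint drift; `111·β̂` is the shift in km/yr,
  with a likelihood-ratio test on the year term.
* **Community tests** — Shapiro–Wilk gate, then a one-sample t-test or a
  Wilcoxon signed-rank test with the Hodges–Lehmann pseudomedian (median
  of all Walsh averages) and signed-rank confidence interval.
* **Thermal-envelope shifts** — a two-part (hurdle) GAM per species:
  binomial presence part and Gaussian log-biomass part on smooths of
  bottom temperature, surface temperature and depth (optionally sea
  ice). Grid predictions use the Duan smearing retransformation,
  `b = p·e^u·Φ` with `Φ = Σ e^{εᵢ}/n`; the trend of the b-weighted
  projection centroid is the envelope shift rate.
* **Tracking & traits** — Pearson correlation between observed and
  envelope shifts, sign-correspondence tables, frequency-ordered
  incremental correlations, and trait regressions by generalized least
  squares with a power variance structure (`Var ∝ |v|^{2δ}`).
* **A synthetic survey generator** with closed-form ground-truth shift
  rates (linear temperature field: every isotherm drifts at
  `warming_rate/|gradient|` °lat/yr), used by the test suite to validate
  every estimator.

## Worked example

Twenty synthetic species with thermal optima laddered across a warming
high-latitude shelf (isotherm drift 15 km/yr; edge-truncated species
shift less in truth):

```r
library(trawlshift)

cfg     <- sim_config(seed = 1)          # 20 species, 20 years, 120 hauls/yr
survey  <- simulate_survey(cfg)
curated <- curate_dataset(survey$hauls, survey$catches, survey$env,
                          region_filter_spec())
shifts  <- estimate_shifts(compute_annual_centroids(curated), region = "demo")
community_shift_test(shifts)
```

```
<community_summary> demo
  n = 20 species; normality p = 0.914 -> t-test
  central shift 8.31 km/yr [6.08, 10.54], p = 2.46e-07
  individually significant: 17 north, 0 south
```

The community mean shift of ~8 km/yr sits between the full isotherm
drift (15 km/yr, interior species) and the truncated rates of
range-edge species, and the near-zero p-value reflects that essentially
the whole community is moving north. Comparing against the generator's
ground truth and adding the thermal-envelope stage:

```r
est <- merge(shifts, survey$truth, by = "species")
mean(abs(est$shift_km_per_yr - est$true_shift_km_per_yr))
#> [1] 0.891

envelopes <- estimate_envelope_shifts(curated, survey$env, region = "demo")
correlate_shifts(shifts, envelopes)
#> $r
#> [1] 0.981
#> $p_value
#> [1] 2.56e-14
#> $n
#> [1] 20
```

Species-level estimation error averages ~0.9 km/yr against truth, and
because these synthetic species track their thermal habitat by
construction, observed and envelope shift rates correlate strongly
(r ≈ 0.98).

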