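---
title: "Estimating marine range shifts from trawl surveys: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating marine range shifts from trawl surveys: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlshift)
```

## The scientific problem

Bottom-trawl monitoring programmes sample fish communities at hundreds of
stations per year over decades. As shelf seas warm, species are expected to
move poleward, but a trawl survey measures a species' position only through
where it happens to be caught: catches are zero-inflated, sampling effort
moves between years, and each species is observed over only part of its
range. `trawlshift` implements an analysis chain that turns haul-level
catch tables into defensible per-species latitudinal shift rates and asks
whether those shifts track the movement of each species' thermal habitat.

The chain has four stages:

1. **Curation** — standardized filters on hauls (depth band, season,
   gear, distance to coast) and a two-pass retention rule on species:
   a year only counts for a species if the species was caught in at least
   `min_trawls_per_year` (default 5) hauls that year, and a species is only
   analysed if it has at least `min_years` (default 10) such years.
2. **Geographic shifts** — annual biomass-weighted centroid latitude and
   depth per species, then a generalized additive model per species.
3. **Thermal-envelope shifts** — a two-part (hurdle) GAM of the species'
   biomass-temperature relationship, projected onto each year's
   environmental grid; the trend of the projected-biomass centroid is the
   shift the species *would* show if it tracked its thermal conditions.
4. **Tracking and traits** — Pearson correlation and sign-correspondence
   between observed and envelope shifts, and generalized least squares
   regressions of shifts on species traits.

## The centroid shift model

For species $s$ in year $t$, the centroid is the biomass-weighted mean
over its presence hauls,

$$\mathrm{lat}_{st} = \frac{\sum_i b_{ist}\,\mathrm{lat}_{ist}}{\sum_i b_{ist}},$$

and analogously for depth using the measured haul depth. The shift model is

$$\mathrm{lat}_{st} = f(\mathrm{depth}_{st}) + \beta_s\,t +
  \gamma_1\,\overline{\mathrm{lat}}^{\,\mathrm{survey}}_t +
  \gamma_2\,\widetilde{\mathrm{lat}}^{\,\mathrm{survey}}_t + \varepsilon_{st},$$

where $f$ is a penalized regression spline (basis dimension 4), and the
two survey covariates are the mean and median latitude of *all* hauls in
the region-year, species present or not. These covariates absorb
interannual movement of the survey footprint: when the sampled window
drifts, a naive trend on centroids confounds species movement with survey
movement, whereas the footprint covariates soak up exactly the component
of centroid movement that co-varies with where the survey went.
$111\,\hat\beta_s$ is the shift rate in km/yr.

Significance of the year term is a likelihood-ratio comparison of the
model with and without $t$, with smoothing parameters held at the
full-model estimates. For this Gaussian model with unknown scale the
comparison is carried out in its exact-F form: the change in deviance over
the full-model scale is referred to $F(1, \mathrm{df_{res}})$, where the
residual degrees of freedom use the smooth's effective degrees of freedom.
A Wald $t$-test on $\hat\beta_s$ is available via `p_method = "wald"`. In
null simulations (no warming, no footprint drift) the likelihood-ratio
form rejects at roughly 5–6% at $\alpha = 0.05$ — a mild residual
anticonservatism from data-driven smoothness selection that we consider
adequately calibrated at these series lengths; a chi-square reference for the raw likelihood ratio would
reject at ~10% on series of ~20 points and is not offered.

Degenerate inputs are handled explicitly: a constant centroid series
returns a zero shift with $p = 1$; a constant depth series drops the
smooth; survey mean and median latitude with correlation above 0.999 drop
the median term (they are then numerically indistinguishable); fewer than
10 annual centroids is a refusal, not a fit.

### Community-level inference

Shift rates across species are tested against zero with a Shapiro–Wilk
normality gate at $\alpha = 0.05$: normal-looking communities get a
one-sample $t$-test and a mean with $t$-interval; otherwise a two-sided
Wilcoxon signed-rank test is used and the location estimate is the
Hodges–Lehmann pseudomedian — the median of all $n(n+1)/2$ Walsh averages
$(x_i + x_j)/2$ — with its confidence interval obtained by inverting the
signed-rank distribution (exactly for $n \le 25$, by normal approximation
above; the threshold is an argument).

## The thermal-envelope model

Catches are zero-inflated, so the biomass-temperature relationship is
estimated in two parts, pooled over all years (the realized envelope is
assumed stable over the study period; only its geographic expression
moves):

* **Part 1 (occurrence):** binomial GAM of presence/absence on smooths of
  sea bottom temperature, sea surface temperature and depth (sea-ice
  concentration optionally, intended for Arctic-influenced regions),
  penalized regression splines with basis dimension 4 per term.
* **Part 2 (abundance):** Gaussian GAM of log biomass on the same
  smooths for the presence hauls only, plus a linear term for the
  species' annual mean biomass, which absorbs year-to-year abundance
  fluctuations so the smooths are not forced to explain them.

Back-transforming a log-scale prediction $e^{\hat u}$ underestimates the
mean; the Duan smearing factor corrects this nonparametrically:

$$\Phi = \frac{1}{n}\sum_{i=1}^{n} e^{\varepsilon_i},$$

the mean of the exponentiated part-2 residuals. Predicted biomass on a
grid cell is then $b = \hat p\, e^{\hat u}\, \Phi$. For each year the
model is projected onto that year's environmental grid (masked to the
region's surveyed depth band), the annual-mean-biomass covariate held at
its training-period mean so that interannual envelope movement reflects
the environment alone. The $b$-weighted centroid latitude of the
projection, regressed on year (OLS, slope × 111), is the envelope shift
rate; the $b$-weighting mirrors the observed-centroid definition so the
two rates are commensurable. Model quality is reported as the in-sample
AUC of part 1 (rank statistic, ties averaged) and the percentage of
deviance explained by part 2.

Prediction at covariate values outside the training range is allowed but
the extrapolated cell fraction is recorded per projection.

## Tracking and trait analyses

Observed and envelope shift rates are compared three ways: a Pearson
correlation over matched species; a four-cell sign-correspondence table
(an exactly zero rate counts as northward — a measure-zero convention);
and an incremental correlation that orders species by number of records
and recomputes the correlation on the top-$k$ species for $k = 3, \dots,
N$, exposing how rarer, noisier species dilute or create the signal.

Trait regressions use generalized least squares with a power variance
structure, $\mathrm{Var}(\varepsilon_i) = \sigma^2 |v_i|^{2\delta}$,
fitted by maximum likelihood (via `nlme`). The variance covariate $v$
defaults to the absolute fitted mean — the conventional reading of a
power-of-the-mean error — with any strictly positive column (e.g.
`n_records`) available as an alternative; the choice is recorded in the
output. Fixing $\delta = 0$ reproduces OLS exactly, which the test suite
uses as an oracle. Following common practice in this literature each trait
is fitted in its own model; the number of records enters as a covariate
when it is itself a significant predictor of the (absolute) shift rates.
Zoogeography contrasts are reported against "Arctic" whenever that level
is present. Raw p-values carry the inference, with a Holm-adjusted column
emitted alongside for transparency.

## The synthetic survey generator

Every estimator above is validated against a generator with closed-form
ground truth. Its mean bottom-temperature field is linear in latitude and
time,

$$T(\mathrm{lat}, t) = T_0 + g\,(\mathrm{lat} - \mathrm{lat}_0) + w\,t,$$

with gradient $g < 0$ (cooler northward) and warming rate $w \ge 0$, plus
iid cell noise. Surface temperature is the bottom field plus a fixed
offset plus an independent noise draw — correlated with but not collinear
to bottom temperature, since exactly collinear fields would make the
hurdle-GAM smooths unidentifiable. Sea-ice concentration is a
deterministic decreasing ramp in bottom temperature clipped to $[0, 1]$.
Species occupy Gaussian thermal niches in bottom temperature: presence is
Bernoulli with probability $p_{\max}\exp(-(T - T_{\mathrm{opt}})^2 / 2
\sigma_T^2)$ and biomass given presence is lognormal, independent of
temperature by default so that presence alone carries the niche and the
expected centroid has a closed form (a biomass-temperature response can be
switched on to stress part 2). Every isotherm drifts north at $w/|g|$
degrees per year, so the true envelope shift is $111\,w/|g|$ km/yr for
every species, and the true geographic shift is obtained by numerically
integrating the expected-biomass-weighted latitude over each year's
sampled window: species whose niche is interior to the window shift at
the full isotherm rate, species truncated by the region edge shift less.
Ground truth uses the noise-free mean field, as the noise is mean-zero
and truth is an expectation.

### Default scenario

The default configuration emulates a high-latitude shelf survey at desk
scale: 20 species, 20 years, 120 hauls/yr in an 8° × 20° box sampled in
months 7–9, a 0.25° environmental grid, gradient −0.5 °C/°lat, warming
0.0675 °C/yr (isotherm drift 15 km/yr — the upper end of what the
estimators should recover), cell noise 0.3 °C, thermal optima laddered
from 1 to 6.5 °C with breadth 0.7 °C so that the community spans
interior species (true shift ≈ 15 km/yr) through strongly edge-truncated
ones (a few km/yr), peak presence probability 0.85 and log-biomass sd
0.6. Species whose true shift would be ~0 sit essentially outside the
sampled region and are (correctly) removed by the retention filters, so
the estimable community spans roughly 3–15 km/yr. The default bathymetry
varies with longitude only: the generator gives biomass no depth
response, so the depth field's form is free, and making it independent of
latitude keeps the centroid-depth covariate exogenous to the
centroid-latitude sampling noise — with a latitude-sloped bathymetry the
two share sampling error and the year term's null rejection rate inflates
to ~6.5% even in an exact linear model, which would confound calibration
checks of the estimator with endogeneity robustness. Users can supply any
`depth_field`.

One master seed drives deterministic per-stage child seeds, so adding a
species never perturbs the haul positions, and all outputs are
byte-reproducible.

### What the generator does not emulate

Real surveys have gear changes, catchability drift, spatially correlated
temperature anomalies, currents and advection, species interactions,
seasonal migration and vertical (depth) habitat shifts. Passing the
validation suite therefore shows that the estimators recover known shifts
under clean sampling with realistic zero-inflation, footprint drift and
niche truncation — not that they are unbiased on any particular real
survey. In particular, the depth smooth is exogenous here by design; on
real data, depth-latitude correlation can couple the depth covariate to
centroid noise and mildly inflate significance (see above), which is a
property of the centroid model itself, not of the implementation.

## Validation study sizes

The packaged validation (test suite and `scripts/acceptance.R`) uses: 200
replicates of the default warming scenario for shift-rate recovery (mean
absolute error and 95% CI coverage against ground truth) and 200
replicates of the null scenario for calibration in the test suite, with
60 replicates of each in the acceptance script's quicker summary; 8
replicates of a footprint-drift-only scenario comparing corrected and
uncorrected community estimates; 100 hurdle-lognormal datasets for the
smearing-vs-naive bias comparison; single full runs for envelope tracking
(Pearson r between observed and envelope shifts); and n = 1000 for the
GLS variance-power recovery. These sizes were chosen so the whole
validation runs on one CPU in minutes while leaving Monte Carlo error
well below the margins being asserted.

## Known limitations

* Shift rates use the fixed conversion 111 km/° latitude; longitudinal
  shifts are out of scope.
* Centroid depth is computed and stored but its trend is not modelled.
* The envelope model assumes a time-stable realized niche; a drifting
  niche would bias envelope shifts toward zero.
* AUC is in-sample, as conventional for explanatory (not predictive)
  species distribution models; it overstates out-of-sample skill.
* The two-pass retention filter censors exactly the rare, fast-moving
  edge species whose shifts are largest in truth; community-level
  estimates are therefore estimates for the *retained* community.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
survey <- simulate_survey(cfg)
curated <- curate_dataset(survey$hauls, survey$catches, survey$env,
                          region_filter_spec())
centroids <- compute_annual_centroids(curated)
shifts <- estimate_shifts(centroids, region = "demo")
community_shift_test(shifts)

envelopes <- estimate_envelope_shifts(curated, survey$env, region = "demo")
correlate_shifts(shifts, envelopes)
```
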