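---
title: "Modelling daily locust density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily locust density: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`locustgam` estimates daily density of the Australian plague locust
(*Chortoicetes terminifera*) from roadside survey records joined to gridded
environmental data. This vignette explains the statistical model, the
choices behind each stage, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## The estimation problem

Field officers drive transects and record, at roughly 10 km intervals, an
ordinal *density class* (absent, isolated, scattered, numerous,
concentrated, swarm) and the life stage observed (nymph or adult). The goal
is a continuous density estimate, in individuals per square metre, for any
grid cell and day, together with its uncertainty. Two features make this
harder than a standard species-distribution problem: the response is
ordinal and survey-derived rather than a count from a designed protocol,
and coverage is sparse and biased toward roads.

## From ordinal classes to a continuous response

`sample_density()` converts a class code into a continuous density by
drawing from a normal distribution centred on the class midpoint with
standard deviation 30% of the midpoint; negative draws are rejected and
redrawn. Absence (class 0) is always exactly 0. Two consequences matter:

* the 30% coefficient of variation is a *ceiling on attainable accuracy*:
  no model fitted to these draws can beat the noise injected here;
* rejection (rather than truncation with a point mass at zero) keeps the
  class-conditional mean at the midpoint and reserves zero for true
  absence. For classes whose midpoint exceeds three standard deviations
  the rejection correction is negligible.

The default scheme (`default_class_scheme()`) uses log-spaced midpoints
0.05, 0.5, 5, 25, 75 individuals/m^2 with interval bounds at geometric
means of adjacent midpoints. The real programme's class table is not
public; the scheme is an explicit, replaceable configuration object.

The model response is `density^(1/6)` (`power_transform()`). A power
transform is used instead of a log because absences map to 0 and stay in
the model; 1/6 compresses the heavy upper tail strongly while remaining
invertible.

## Covariate engineering

For each survey, `build_feature_table()` computes, from the nearest grid
cell (nearest centre in degrees; ties to the lower index):

* min/max/mean of maximum temperature, minimum temperature, rain, vapour
  pressure and solar radiation over two memory windows — 10 days (short)
  and 60 days (long) — each *inclusive* of the survey date, i.e. 11 and
  61 daily values. The inclusive convention follows the worked example of
  a 10-day window ending 15 March spanning 5–15 March. Rain minima are
  omitted (essentially always 0);
* counts of dry days (rain = 0 mm), days with minimum below 18 °C and days
  with maximum above 42 °C, for both windows — thresholds adapted from
  locust ecophysiology (development limits);
* monthly NDVI (rows with negative NDVI, i.e. water/cloud artefacts, are
  dropped and counted), static clay/sand/silt fractions, and astronomical
  daylength from the standard solar-declination formula
  (declination `-23.44 cos(2*pi*(doy+10)/365)`; agrees with a
  NOAA-series oracle to under 0.1 h at study latitudes).

This yields 39 candidate covariates: 5 weather variables x 2 windows x 3
statistics − 2 rain minima + 6 threshold counts + NDVI + daylength + 3
soils. The *full* model removes 12 (all six tmin summaries, both rain
maxima, the 10-day tmax min/max, both dry-day counts — low t-statistics or
high correlation with retained covariates), leaving 27; with longitude,
latitude and day of year in the tensor the full model uses 30 variables.
The *reduced* set keeps 10 covariates of highest importance or ecological
interest. Only the sizes (39/27/10/30) are contractual; the exclusion list
is a configurable default because the original enumeration is not fully
recoverable.

For the linear screening models the covariates are standardized to
training-set mean 0 / sd 1 (`standardize_features()`); holdout rows reuse
the training statistics, and a second application is refused. The GAM
consumes unscaled covariates.

## Feature selection

Four linear screens of the transformed response run on the standardized
design: Gaussian OLS, ridge (exact SVD solution; penalty by tenfold CV on
a grid), lasso (glmnet coordinate descent; tenfold CV with the
one-standard-error rule on a 100-point grid descending four decades from
`lambda_max`) and bidirectional stepwise AIC from the full model. Variable
importance is `|t|` normalized to sum to 100% per method. Penalized fits
have no canonical t-statistics, so ridge/lasso importances use a
post-selection OLS refit on the active set — an explicit substitute,
recorded in the fit metadata. The Gaussian family for this stage is itself
a choice: the screening response is the continuous transformed density.

## The abundance GAM

The core model is a generalized additive model with

* negative binomial response family and **square-root link**: the mean is
  `mu = eta^2` where `eta` is the additive predictor. Unlike a log link,
  back-transformation squares rather than exponentiates, which tempers
  extrapolation in sparse regions;
* cubic regression spline smooths (k = 10, second-order penalty,
  sum-to-zero constraint) for each covariate, with no covariate-covariate
  interactions;
* one tensor-product smooth over (unscaled) longitude x latitude x
  day-of-year — marginal bases cubic, cubic, cyclic with period 366 so the
  year wraps continuously — absorbing spatial and seasonal structure not
  captured by the environmental covariates;
* smoothing parameters by (f)REML through mgcv (`gam`, or `bam` for the
  large/continuous-response fits), the same numerical machinery the
  original analysis used.

Two response scales are supported, because the combination "negative
binomial family + sixth-root-transformed response" is unusual (a count
family applied to a continuous quantity):

* `response_scale = "density"`: NB on the count-like density itself, with
  dispersion `theta` profiled. This is the statistically conventional
  path and the one used for parameter-recovery testing;
* `response_scale = "sixth_root"` (default, mirroring the stated
  configuration): NB quasi-likelihood on the continuous transformed
  response. This response is *underdispersed* relative to any
  finite-`theta` negative binomial, so the `theta` profile either
  diverges toward the Poisson limit or sticks at a poor interior mode. The
  engine therefore pins `theta` at `1e5` (the stable near-Poisson limit)
  on this scale; `fit_abundance_gam(theta = NA)` restores profiling, and
  any pinned-dispersion convergence chatter from the scale loop is
  recorded in `model$warnings` rather than raised.

`response_curves()` returns each smooth's centred contribution with a
±2 sd band and a signal-to-noise mask (true where the standard error is
below half the absolute response, SNR ≥ 2) — the region recommended for
interpretation. `tensor_slices()` evaluates the space–time tensor at a
fixed day of year; slices at day 1 and day 366 coincide by construction.

## Evaluation protocol

`make_split()` holds out 20% of rows; the remaining 80% is partitioned
into ten folds, so each CV iteration trains on 72% of all rows and tests
on 8%. Cross-validation is for model/hyperparameter choices; reported
metrics come from the 20% holdout. Life-stage subsets (nymph-only,
adult-only, all rows including absences) are applied before splitting.
Metrics: AIC from the fit, R^2 as deviance explained, RMSE on the
transformed scale (the model's estimand; the report records the scale),
and Spearman/Kendall rank correlations with average-rank ties.

## Mapping and uncertainty

`predict_grid()` engineers covariates for every grid cell exactly as for
surveys, predicts, and back-transforms to density. Its uncertainty
combines two sources, reported separately and summed on the variance
scale:

* model variance by the delta method through the link and back-transform
  (`d mu / d eta = 2 eta`, plus the power-transform Jacobian when the
  sixth-root path is active);
* class-sampling variance: the variance of the ordinal-to-continuous
  conversion at the predicted class, estimated by Monte Carlo (default
  200 draws, fixed seed).

`uncertainty_fraction` is the combined standard error divided by the
estimate. Cells farther than 50 km (haversine, spherical Earth 6371 km)
from any ever-surveyed site are masked (`proximity_mask()`);
`bivariate_classify()` then bins unmasked estimates and uncertainty
fractions into per-date terciles for a blue (density) x yellow
(uncertainty) bivariate map: bright blue = high density / low uncertainty,
bright yellow = the reverse, grey blend = high on both. Tercile edges are
recorded on the object. `rmse_map()` aggregates holdout residuals into
coarse cells.

## The synthetic-data generator

No public archive of the survey records exists, so `generate_env_grid()` /
`generate_surveys()` produce inputs with the statistical structure the
pipeline assumes:

* weather: AR(1) daily anomalies (lag-1 coefficient 0.8) around an austral
  seasonal cycle, spatially smoothed innovations (Gaussian kernel over
  cells), rain zero-inflated (~70–75% dry days) with bounded
  exponential-tail amounts, vapour pressure coupled to minimum
  temperature, radiation depressed on wet days, `tmax >= tmin` enforced
  through a positive diurnal-range field;
* monthly NDVI in (−0.2, 1] with a small negative share so the NDVI
  filter is exercised; static soil fractions positive with sum below 1;
* surveys: September–May dates; locations a mixture of uniform background
  and points along random piecewise-linear transects at ~10 km spacing
  (`roadside_bias` mixing weight), coordinates recorded at 0.01°;
* latent abundance *additive on the square-root scale* — the same scale
  the GAM works on, so the generator's truth is exactly the model's
  estimand: `eta = eta0 + sum_j f_j(x_j) + spatial field + seasonal
  cycle`, floored at 0.05 (the link needs a positive mean), `mu = eta^2`,
  negative binomial counts, binned by the class scheme;
* `detection_prob`: optional survey-level detection failure (locusts
  present but missed from the road record an absence). The default is 1;
  tests that need realistic covariate-independent zeros set it below 1;
* `eta0 = 0.52` was calibrated once so that roughly a third of surveys
  are positive (matching the surveyed programme's long-run rate) and then
  frozen.

What the generator does **not** emulate: migration and wind transport,
egg diapause and multi-generation dynamics, the geometry of the real road
network, observation-station interpolation error in the weather fields,
and any real spatial covariance between weather variables. Tests passing
on synthetic data therefore demonstrate that the *pipeline* recovers
structure it is pointed at — not that the fitted ecological relationships
transfer to the real system.

## Numerical choices and degenerate inputs

* Problem sizes: the test-suite and acceptance runs use 5,000–6,000
  surveys on a 41 x 41-cell grid over one year, with tensor margins
  (6, 6, 5) or smaller; the analysis scripts fit the 27-smooth full model
  with k = 6 per covariate so the coefficient count stays proportionate
  to the synthetic sample size.
* `fit_abundance_gam()` refuses (by default) fits with fewer than 10
  observations per coefficient.
* Nearest-cell ties break toward the lower index; the window is inclusive
  of the survey date; dry means rain exactly 0 mm.
* Degenerate bivariate fields (near-constant estimate or uncertainty)
  fall back to a single bin with a warning; empty stage subsets, unknown
  class codes, sites outside the grid, zero-variance columns and
  rank-deficient designs raise informative errors.
* Predictions clamp covariates to the training range and report the
  clamp count rather than extrapolating splines.

## Known limitations

* The NB-on-continuous-response configuration is reproduced as specified,
  but its deviance-based R^2 is not comparable across response scales;
  the comparison table records which scale each row used.
* Variable importances for penalized methods depend on the post-selection
  refit convention.
* The 12-name exclusion list and the class scheme are defensible defaults,
  not recovered ground truth.
* Grids are exported as CSV (plus JSON sidecars); no GeoTIFF/NetCDF
  export is provided.
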