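---
title: "Deriving drought-resistance indicators from phenotyping time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving drought-resistance indicators from phenotyping time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtphen)
```

## The problem

Drought resistance of a plant accession is not one number. Screens that only
compare biomass under drought against well-watered controls miss evasion and
tolerance mechanisms that show up in water use, tissue water content,
chlorophyll, and root allocation. `droughtphen` implements a
multi-indicator analysis for high-throughput phenotyping screens of bean
accessions (Phaseolinae: *Vigna*, *Phaseolus* and relatives) grown under a
stop-watering protocol: pots are watered to field capacity (volumetric soil
moisture around 0.60), watering then stops so that moisture declines while
the plant keeps transpiring, and each pot is rewatered once its moisture
falls below a 20% threshold, with one recovery measurement afterwards.
Imaging happens on a fixed days-after-sowing (DAS) schedule
(18, 25, 29, 33, 36, 39, 43, 46 by default), giving per-plant time series of
projected shoot area (mean of six side views), projected root area
(bottom view), soil moisture, and reflectance in four bands.

From these series the package derives five per-accession indicators,
analyses their correlation structure, partitions their variance within and
between subgenera, clusters accessions by response profile, and relates the
indicators to the climate at each accession's collection site.

## The five indicators

**Biomass penalty.** The proportion of projected shoot area lost to
drought, $(\bar A_{ctrl} - \bar A_{drought})/\bar A_{ctrl}$, computed from
the drought plants' post-rewatering measurement (avoiding drought-induced
leaf rolling) against the control-arm mean on the same day. Because plants
of one accession are rewatered on different days, each drought plant is
matched to the control mean of *its own* rewatering day and the per-plant
penalties are averaged. A negative penalty means drought plants outgrew
controls; values are capped above by 1 ($A \ge 0$).

**Soil moisture at wilting (WUE curve).** With watering stopped, the
decline in soil moisture between two measurements is a proxy for water
consumed, so each drying interval yields a water-use-efficiency point
$\mathrm{WUE} = (A_{t2}-A_{t1})/(m_{t1}-m_{t2})$ plotted at the interval's
mean moisture. Positive WUE is growth, negative is wilting. Intervals over
which moisture rose (rewatering) are excluded — the quotient presumes
drying. Points are pooled over the accession's drought plants and a smooth
*monotone increasing* curve is fitted: an I-spline basis (integrated cubic
B-splines) with three interior knots at the moisture quantiles
0.25/0.5/0.75, non-negative basis coefficients (solved by non-negative
least squares) and a free intercept. The indicator is the curve's
x-intercept (WUE = 0), located by bisection; monotonicity makes the
crossing unique. Curves that never cross zero yield a sentinel
(`below_range`/`above_range`) recorded as a missing value with a reason
code — never clamped to a range edge — so downstream analyses filter
explicitly.

**Soil moisture at leaf desiccation (RWC index).** Water absorbs short-wave
infrared light, so the reflectance ratio $r_{1528}/r_{1417}$ tracks leaf
relative water content; the ratio is invariant to overall illumination. The
index is flat while the leaf is hydrated and declines once soil moisture
drops below a critical value. A linear-plateau model
$y = a + b\,\min(x, x_0)$ (linear up to the junction $x_0$, constant above)
is fitted to the pooled (moisture, index) points and $x_0$ is the
indicator.

**Soil moisture at chlorosis (NDVI).** Identical machinery on
$(r_{800}-r_{680})/(r_{800}+r_{680})$, the normalised difference vegetation
index, a proxy for relative chlorophyll content.

**Root/shoot ratio.** The mean over plants of the per-plant ratio of
projected root to shoot area at the first measurement day, before drought
onset (root imaging through the pot bottom is unreliable once soil dries
and pulls away). Mean-of-ratios is used, not ratio-of-means: each plant is
one observation of the allocation trait.

For all four moisture indicators, **lower is more resistant** (the plant
holds out longer into the dry-down); a higher root/shoot ratio is read as
potentially more drought-adapted.

## Fitting the linear-plateau model

The RSS surface of the breakpoint model is smooth in $x_0$ only between
order statistics of $x$, so the fit proceeds in three stages: (1) profile
the junction over the midpoints of adjacent distinct $x$ values (plus
$\max x$, the unbroken-line limit), solving the conditional OLS in $(a,b)$
exactly at each candidate; (2) minimise the profiled RSS continuously
inside each segment (sub-grid plus 1-D search); (3) polish $(a, b, x_0)$
jointly with the Levenberg–Marquardt algorithm, keeping the best profiled
solution if LM does not improve it. The returned RSS is therefore never
worse than the best plain-linear or constant fit, and the test suite holds
it to an exhaustive brute-force profiling oracle at $10^{-6}$ relative.

Two QC rules guard interpretation. The junction is only meaningful if the
index is flat at high moisture and *declines* below the junction, so fits
with $b \le 0$ (plateau at low moisture) are flagged. And the indicator is
defined as the moisture where the index starts dropping *significantly*:
when the plateau model does not beat a constant fit in a partial F-test at
$\alpha = 0.05$ — which happens when the true junction sits at or below the
observable moisture floor, leaving no decline segment — the junction is
unidentified and would otherwise drift into the plateau. Flagged junctions
are recorded as missing with their reason code. Junctions within
$10^{-6}$ of the observed moisture range edge, and non-converged fits, are
flagged for the same reason.

## Statistical analyses

* **Descriptives** (N, min, max, mean, sd with $n-1$, variance) per
  indicator over non-missing accessions.
* **Spearman correlations** between all indicator pairs, average ranks for
  ties, two-sided p from the large-sample t approximation (exact
  permutation distribution below 10 pairs), Bonferroni-adjusted over the
  $k = 10$ pairs.
* **Variance partitioning**: for each indicator, the one-way random-effects
  model $y_{ij} = \mu + b_i + e_{ij}$ with $b_i \sim N(0, \sigma^2_b)$ and
  a *separate* residual variance per subgenus,
  $e_{ij} \sim N(0, \sigma^2_i)$, fitted by REML. Groups are independent
  given $b_i$, so the REML criterion has a closed group-wise form via the
  Woodbury identity, optimised over log-variances (L-BFGS-B with a
  Nelder–Mead polish; variances floored at zero and flagged singular).
  Subgenera with three or fewer accessions are dropped beforehand. The
  reported quantity is the within/total proportion
  $\sigma^2_i/(\sigma^2_b+\sigma^2_i)$, using each subgenus's own residual
  variance in the denominator (a deliberate choice; a pooled denominator is
  the other defensible reading). REML rather than ML matches standard
  mixed-model practice; the implementation is cross-checked against
  `nlme::lme` with `varIdent` in the tests.
* **Clustering**: Manhattan distances over the five indicators
  (complete-case rows, dropped accessions logged), Ward agglomeration in
  the classic `ward.D` dialect — the Lance–Williams update applied to the
  *unsquared* dissimilarities, the historical behaviour when a precomputed
  Manhattan matrix is handed to the clustering routine. The
  squared-dissimilarity dialect is available behind a flag. The tree is cut
  at five clusters, a choice supported by the within-cluster
  sum-of-squares scree.
* **PCA** on the covariance of the centred, *unscaled* indicator columns
  (they share similar ranges, so no transformation is applied; scaling is a
  flag). The Kaiser count for covariance PCA is the number of eigenvalues
  above the mean eigenvalue.
* **RDA**: the centred indicator matrix is regressed on the standardised
  climate variables (annual mean temperature, temperature seasonality,
  annual precipitation, precipitation seasonality, isothermality — units
  are incommensurable, hence the standardisation; the indicator side is
  centred only, mirroring the PCA choice). The fitted values are
  SVD-decomposed into constrained axes; $R^2$ is the fitted share of total
  variance and the adjusted $R^2$ uses the Ezekiel correction. Inference
  permutes the *rows of the climate matrix* (residual-permutation schemes
  are the alternative; row permutation is the simpler exchangeable-null
  choice) with 999 permutations and the add-one convention
  $p = (1 + \#\{stat_{perm} \ge stat\})/(1 + P)$, whole-model and per-axis.
  The implementation is cross-checked against `vegan::rda` and
  `RsquareAdj` in the tests. Pearson indicator-climate correlations with
  0.05/0.01 star coding complete the climate analysis.

Soil moisture is held internally as a volumetric fraction in $[0,1]$;
file I/O accepts and emits percent behind an explicit unit flag, because
mixing the two scales silently is the classic way to be wrong by 100x.

## The synthetic experiment generator

Real screens of this kind are large one-off datasets; the package instead
ships a generator whose ground truth makes every downstream stage testable.
Per accession it draws a latent resistance score (iid standard normal) and
derives the true indicator values from it: wilting moisture
$0.34 - 0.036\,z$ (sd 0.05 total), desiccation moisture $0.31 - 0.045\,z$
(sd 0.08), chlorosis moisture $0.39 - 0.050\,z$ (sd 0.09), penalty
$\mathrm{logit}^{-1}(\mathrm{logit}(0.62) - 0.55\,z + \ldots)$ (sd about
0.19), and a lognormal root/shoot ratio centred near 0.08 — magnitudes
typical of bean screens, with resistant accessions (high $z$) getting
lower indicator values throughout. Between-subgenus structure enters as
per-indicator subgenus offsets drawn once from a fixed pool of twelve
subgenera, standardised to their nominal variance and mutually
orthogonalised under the sampling weights — without that, the twelve-level
pools would carry a random cluster-level cross-covariance into every
indicator pair that no sample size removes. Annual precipitation is drawn
so that its correlation with the latent score hits the configured coupling
(default $-0.45$: resistant accessions come from arid sites, so the
indicators come out positively related to precipitation); the other four
climate variables get plausible couplings to precipitation and
temperature. Climate is only generated for wild accessions with usable
collection coordinates (about 92% of the wild ones), matching how such
analyses shrink to a subset.

Plant-level series follow the protocol. Drought-pot moisture decays
piecewise-exponentially at daily rate $\alpha(1 + A/1500)$ with
$\alpha = 0.05$/day — larger plants dry their pots faster, and this
calibration puts most threshold crossings at 29–43 DAS with a spread
across plants, as on a real platform. Noise enters the drought series as
lognormal jitter on the decay rate (so the series stay physically
non-increasing between rewaterings) and as truncated additive noise around
field capacity for controls. Shoot growth is logistic with the
per-interval rate multiplied by
$g(m) = \mathrm{clamp}((\bar m - \theta_w)/0.12,\ -0.3,\ 1)$, so interval
WUE changes sign exactly at the true wilting moisture. The clamped-linear
$g$ is an artifact choice — the real moisture-growth link is unknown — and
is the main reason recovery tests certify the estimator, not the biology.
The spectral indices are generated on plateau-then-linear-decline curves
with the true breakpoints and inverted back into band reflectances, which
are clipped into $[0,1]$ with clipping events logged. The post-rewatering
shoot area encodes the accession's true biomass penalty relative to the
deterministic control trajectory, emulating the recovery measurement.

Randomness uses L'Ecuyer-CMRG parallel streams: stream 0 carries the
shared pools, stream $i$ the $i$-th accession, so output is byte-identical
for a given seed and adding accessions never perturbs existing ones.
(Seeding many Mersenne–Twister streams from related integers induces
measurable cross-stream correlation; CMRG streams are built for this.)

What the generator does *not* emulate: radiative-transfer realism in the
reflectances, pot microclimate, germination and dormancy, imaging
artefacts beyond simple noise, and any moisture-growth link other than the
clamped-linear one. Passing recovery tests therefore demonstrate that the
estimators invert the generative model at realistic noise — they do not
validate the biology of any particular real screen.

## Imaging module

A deliberately simplified, openly documented analogue of the commercial
machine-vision toolchain such platforms use, operating on synthetic
rasters with known ground truth. Shoot segmentation is an HSV colour
filter (green hue band, saturation/value cut-offs) with optional
morphological opening/closing and connected-component size filtering; on
clean rendered silhouettes recovery is pixel-exact, and under 1%
salt-and-pepper noise the count error stays within 2% with the default
settings (morphology off, component filter at 9 px — opening can erode
single-pixel features of a clean silhouette, so component filtering is the
default speckle control). Root segmentation finds the pot disc as region
of interest (largest bright component, holes filled, rim eroded), divides
the image by a Gaussian-blurred version of itself to cancel multiplicative
illumination, and thresholds that ratio — which is why uniform brightness
changes leave the count nearly unchanged. The component-size filter
defaults to 1 px for roots: strands are one pixel wide and fragment under
4-connected labelling. Pixel-to-area calibration divides a plate's known
physical area by its segmented pixel count.

## Numerical choices and degenerate inputs

* Monotone fit: at least 5 points spanning at least 0.05 moisture;
  monotonicity certified on an 801-point grid at $10^{-10}$; bisection
  tolerance $10^{-12}$; a linear trend is exactly representable in the
  I-spline basis, so noiseless linear input recovers its intercept to
  better than $10^{-6}$.
* Plateau fit: at least 4 points, error on constant $x$; LM gradient
  tolerance $10^{-10}$, at most 200 iterations, non-convergence returns
  the best profiled solution flagged `converged = FALSE`.
* REML: log-variance parameterisation, variances below $10^{-7}$ floored
  to zero and flagged singular; constant input returns all-zero components
  directly.
* Ties in Ward merges break deterministically (lowest pair index);
  identical configurations re-run byte-identically, which the pipeline
  records via a configuration hash and seed in every output header.
* Test and acceptance problem sizes are package choices balancing
  statistical resolution against runtime: 100-accession recovery runs,
  100-instance breakpoint oracle sweeps, 8-point brute-force clustering
  oracles, and a 200-replicate null calibration of the RDA permutation
  test at 199 permutations.

## Known limitations

The biomass penalty presumes the projected-area-to-biomass relation is
linear and stable across accessions; absolute biomass is never estimated.
The WUE construction uses soil-moisture decline as the water-consumption
proxy, which folds evaporation into consumption. The root/shoot ratio sees
only peripheral roots at the pot bottom. Breakpoint indicators whose true
junction lies below the rewatering threshold are structurally unobservable
under this protocol and surface as QC-flagged missing values rather than
numbers. Finally, all calibration targets of the generator are plausible
magnitudes, not fits to any particular dataset.
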