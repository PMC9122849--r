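---
title: "Diet-weighted floral resource availability and landscape models of crop pollination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-weighted floral resource availability and landscape models of crop pollination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floravail)
```

## The model

Crop pollination by wild bees depends on what else flowers in the
surrounding landscape, and *when*. Resources that flower before the crop
build up pollinator populations; resources synchronous with the crop can
either compete for visits or concentrate pollinators. `floravail`
quantifies this with a pollinator-specific availability index

$$\mathrm{fai}_{l,t} = n \sum_{p=1}^{P} cr_{p,l} \, vr_{p,t},$$

where $n$ is the number of landscapes, $cr_{p,l}$ is landscape $l$'s share
of the total (across-landscape) cover of plants providing pollen type $p$,
and $vr_{p,t}$ is the share of type $p$ in the pollinator's pollen diet (by
volume) in period $t$. Because each type's cover shares sum to 1 across
landscapes and the diet weights sum to 1 across types, the index averages
exactly 1 over landscapes: it is a *relative* measure, and a landscape with
$\mathrm{fai} = 1.3$ offers 30% more of the pollinator's preferred
resources than the average landscape in the set. A corollary used
throughout is that pollen type $p$ contributes exactly $vr_{p,t}$ to the
aggregate index $\sum_l \mathrm{fai}_{l,t}$, which is what makes the
contribution decompositions (wild vs cultivated, woody vs herbaceous plant
groups) exact identities rather than estimates.

Assumptions worth stating explicitly: cover in m² is a fair proxy for
resource quantity within a pollen type; the diet table (pollen volumes per
type and period) is representative of the pollinator community of interest;
and periods are categorical labels — there is no phenology model, so a type
either belongs to a period or it does not.

## Normalization choices

The diet of a generalist bee contains more pollen types than any field
campaign can map. We renormalize the diet weights over the *mapped,
positive-cover* types in each period, so the mean-1 property of the index
holds exactly for the mapped flora; `vr_include_unmapped = TRUE` keeps the
raw diet shares instead, in which case the mean index falls below 1 by
exactly the unmapped diet fraction — useful as a sensitivity check, not as
the default. Pollen types with zero mapped cover in a period are dropped
with a message (their cover share would be 0/0) and the weights
renormalized. Period membership comes from the diet table's rows, not from
the volumes, so a type can be listed for a period with volume 0. The pooled
period sums each type's volumes across the seasonal periods *before*
normalizing.

## The statistical stage

The pollination response is the mean number of developed seeds per pod,
per landscape, over pods with at least one developed seed — the harvest
definition; `include_zero_pods = TRUE` switches to the all-pods mean.
Modelling is deliberately plain: one observation per landscape, Gaussian
OLS, no mixed effects, no multiple-testing correction, two-sided p values.

Predictors are standardized by dividing centred values by **two** standard
deviations (sample, $n-1$), giving them sd 0.5 so that coefficients of
continuous and binary predictors are comparable. Model comparison uses the
small-sample criterion
$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$
with $\ell$ the Gaussian maximum likelihood (variance estimated as
RSS/$n$ — required for IC consistency) and $k$ counting intercept, slopes
and the residual variance. All predictor subsets are fitted (dredge-style;
a guard refuses more than 12 predictors unless raised), ranked by AICc;
ties are broken by fewer predictors, then lexicographic model labels.
Models within $\Delta < 2$ of the best are retained, and Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ are computed over the full
candidate set. The comparison between mapping approaches reports the
$R^2_{mult}$ / $R^2_{adj}$ of each approach's most parsimonious model on the
identical response vector; the coarse land-cover pool merges
arable + permanent crops into `crop` and the three semi-natural classes
into `snh`, while the fine pool uses all six classes plus, by default, the
center-to-forest and center-to-urban distances (`include_distances = FALSE`
drops them). The unit-sum remainder class `other` is never a predictor.

AICc requires $n - k - 1 > 0$, so selection over single-predictor
candidates needs at least five landscapes; `run_all()` skips the selection
stage with a notice below that, which is why the two-landscape teaching
fixture produces an index table and a response but no selection table.

## Landscape composition inputs

Composition is first-class as a table of class proportions (plus the two
distances). A convenience path accepts labelled planar polygons in a
meter-based coordinate system — there is deliberately no reprojection, to
avoid silent CRS errors. Class areas within the default 500 m disc are
computed by clipping each polygon against a regular 720-gon representation
of the disc (Sutherland–Hodgman); proportions use the polygonal disc area
as denominator, so the arc discretization cancels to first order and
agrees with a fine rasterization oracle to well under $10^{-3}$. Uncovered
area is assigned to `other`, keeping the unit-sum invariant exact. If
polygons of different classes overlap, the later-listed polygon wins after
a warning, with areas re-measured on a fine point grid (an auditable,
deterministic rule for a situation the data model discourages). Distances
are exact point-to-segment minima, 0 if the center lies inside a patch.

## What the synthetic generator emulates

`generate()` draws a full input bundle with the statistical structure the
analysis assumes, at the study's design scale:

* 24 landscapes of 500 m radius, arable-dominated (logistic mean 0.70),
  remaining area split over the other five classes plus `other` by a
  Dirichlet draw weighted toward herbaceous semi-natural habitat;
* 8 preceding and 6 synchronous pollen types with Dirichlet-like diet
  volumes, annotated so early resources are mostly woody and wild (the
  fruit-tree / maple / willow pattern) with a couple of cultivated types;
* species covers log-linear in a landscape floral axis that mixes a shared
  "agricultural intensification" gradient (which also drives the arable
  proportion) with an independent latent, so the arable-vs-preceding-index
  correlation targets `rho_arable_fai` (default −0.6; achieved mean −0.62,
  sd ≈ 0.15 across seeds — the mixing weight carries a fixed 1.15 factor
  compensating the attenuation of the logistic and exponential links);
* landscape mean seeds/pod
  $\mu_l = \beta_0 + \beta_{pre} z(\mathrm{fai}_{pre}) + \beta_{urb} z(\mathrm{urban}) + \varepsilon$,
  with $z$ the two-SD standardization, defaults $\beta_0 = 2.5$,
  $\beta_{pre} = 0.17$, $\beta_{urb} = 0.18$, $\sigma = 0.2$ (treated as a
  between-landscape sd), and the index recomputed *from the generated
  tables*, so the full pipeline recovers the coefficients without bias;
* pod counts drawn as Binomial(8, $p_l$) with $p_l$ solving
  $8p/(1-(1-p)^8) = \mu_l$ — the zero-truncated mean — because the
  response is defined over pods with ≥ 1 seed. Zero-seed pods then occur
  naturally and exercise the harvest filter, and the generating model stays
  consistent with the measurement definition (a plain binomial mean would
  bias slope recovery by the truncation factor, about 15% at these values).

All randomness flows from the single `seed`; written tables carry it in a
header comment.

Features of real data the generator does **not** emulate: spatial
autocorrelation between neighbouring landscapes, pollinator foraging
behaviour, year effects, overdispersed or correlated pod counts within a
plant, and any direct mechanistic link between land-cover classes and
specific plant species. One structural divergence to keep in mind when
reading simulated outputs: because the non-arable classes share the
remainder $1 -$ arable, the urban proportion is negatively correlated with
arable and hence *positively* with the floral index in simulations, whereas
field data can show urban and floral availability as uncorrelated. Passing
tests therefore demonstrate the correctness and calibration of the
computational chain under the stated generating model, not ecological
validity on any particular field dataset.

## Calibration experiments

Two Monte-Carlo experiments (run by the acceptance script and the test
suite) check the statistical stage end to end through the generator, the
index and the OLS machinery:

* **Type-I error**: with $\beta_{pre} = \beta_{urb} = 0$, $\sigma = 0.2$,
  the single-predictor test of seed set on the standardized preceding index
  rejects at $\alpha = 0.05$ in ~5% of 1000 replicates.
* **Recovery**: with $\beta_{pre} = 0.17$, $\beta_{urb} = 0$,
  $\sigma = 0.15$, $n = 24$, the mean estimate over 500 replicates sits
  within ±0.02 of 0.17 and the 95% CI covers the truth 92–98% of the time.
  The urban effect is set to 0 here because the experiment isolates the
  preceding-resource effect with a single-predictor fit; with a nonzero
  urban effect the estimate would be structurally confounded (urban is
  negatively correlated with arable, hence positively with the preceding
  index) — an omitted-variable fact about the design, not a failure of the
  estimator.

Problem sizes throughout (24 landscapes, 55 pods, 1000/500 replicates) are
the package's chosen study conditions and keep the whole suite fast.

## Numerical choices and degenerate inputs

* Standardization refuses zero-variance predictors by name.
* `fit_ols` refuses rank-deficient designs, listing the collinear columns.
* AICc is `NA` on a fit with $n - k - 1 \le 0$; calling `aicc()` on such a
  fit, or selecting over such candidates, is an error rather than a silent
  ranking on `NA`.
* The truncated-binomial inversion uses `uniroot` at tolerance $10^{-10}$;
  latent means are clamped to $[1.05, 7.9]$, inside the truncated-mean
  range $(1, 8)$.
* Selection ties (exactly equal AICc) break toward fewer predictors, then
  lexicographic labels, making output order deterministic.
* CSV outputs are rounded to 4 decimals at serialization only; the JSON
  run report keeps full precision.

## Known limitations

The package fits no pod-level or mixed models (one observation per
landscape, by design), no interactions in the subset selection, and no
spatial statistics. The polygon path handles simple (non-self-intersecting)
polygons only. Reproduction of the original field analysis requires the
archived data deposit to be supplied locally and mapped to the input
schemas (`reproduce_study()`); without it the function reports a skipped
status, and published reference values for the side-by-side comparison are
supplied by the user rather than shipped with the package.
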