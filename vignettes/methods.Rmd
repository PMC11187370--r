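---
title: "Methods: evaluating a citywide 20 mph speed-limit intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a citywide 20 mph speed-limit intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmstreets)
```

calmstreets evaluates a natural experiment: a city lowers the speed limit
from 30 mph to 20 mph on most of its streets, in several implementation
zones, and we ask what happened to police-recorded road traffic collisions
(incidents) and casualties (injured people; one collision can injure
several). The package chains four complementary analyses — road-segment
rate comparisons, matched implementation/control zone comparisons, a
city-level interrupted time series, and an exponential speed–injury
prediction model — over a common spatial-matching and data layer, and
ships a synthetic-data generator so the whole pipeline is testable
without any external data.

## Spatial matching

Collision records carry planar easting/northing coordinates in metres
(British National Grid semantics); all geometry here is Euclidean, with
no geodesic computation anywhere. Each collision is snapped to the road
segment minimising the point-to-polyline distance, provided that minimum
is **at most 12 m** (an inclusive comparison). The 12 m threshold
reflects the positional accuracy of police-recorded coordinates relative
to street centrelines; collisions further than that from every street
are left unmatched rather than forced onto a wrong segment.

Two details are deterministic policies rather than estimates:

* **Ties.** Where two segments are equidistant within 1e-9 m (junctions),
  the lexicographically smallest segment id wins. Junction ambiguity in
  the original setting was resolved by manual map inspection; a pipeline
  needs a reproducible rule, and this one is order-independent.
* **Zone overlay.** Point-in-polygon uses even-odd ray casting with
  boundary points counting as inside. If zones overlap, the
  smallest-area zone wins, again deterministically.

`snap_collisions()` offers a uniform-grid spatial index and a brute-force
all-pairs scan; the index only prunes edges that provably cannot lie
within the threshold, so the two methods are contractually identical and
tests assert record-for-record agreement.

## Rates, percent changes, and difference-in-differences

Street segments are classified from their speed-limit history:
already-20 mph streets (`existing20`), 30-to-20 conversions split into
local and main streets (`changed20_local`, `changed20_main`), streets at
30 mph throughout (`stay30`, the comparison arm), and everything else.

For a count $N$ over an exposure of $T$ years the annual rate is $R =
N/T$. Its confidence interval is the **Garwood (exact Poisson)
chi-square interval applied to the annualized rate value** treated as a
Poisson count:

$$\mathrm{lo} = \tfrac12\chi^2_{\alpha/2}(2R), \qquad
  \mathrm{hi} = \tfrac12\chi^2_{1-\alpha/2}(2R + 2).$$

Applying the interval to the annualized value rather than to the raw
count is the construction consistent with the published tables this
package reproduces; it is documented here as reverse-engineered from
those tables. Continuous $R$ is allowed (annualization rarely gives an
integer) and the lower bound is zero at $R = 0$.

The pre/post difference of rates uses the Poisson count variance scaled
by exposure, $\mathrm{Var} = N_1/T_1^2 + N_2/T_2^2$, with a normal CI.
The percent change $100(R_2/R_1 - 1)$ carries a first-order
(delta-method) SD: since $\mathrm{Var}(R)/R^2 = 1/N$ for a Poisson
count,

$$\mathrm{sd} = 100\,\frac{R_2}{R_1}\sqrt{\frac{1}{N_1}+\frac{1}{N_2}}.$$

The difference-in-differences between a treated arm and the reference
arm subtracts the two percent changes and combines their SDs in
quadrature, assuming independent count streams. $z$ is the exact normal
97.5th percentile (1.959964), not 1.96. Display rounding is
half-away-from-zero; internal computation is never rounded.

One known discrepancy: the per-row percent-change intervals printed in
the source tables do not match any standard delta-method construction we
could reproduce (the point values and the DiD cells all do). The package
emits `value ± z·sd` for those cells and does not force agreement.

Zone comparisons use the same formulas per matched
implementation/control pair, each pair with its own pre/post windows
(the rollout was phased), and a pooled `Total` row whose exposure is the
common window when all pairs share one (otherwise the pair average).

Exposure years are exact day counts / 365.25, with explicit
`pre_years`/`post_years` overrides so nominal values like 3.0 and 1.83
can be forced when reproducing a published table whose rounding
convention is unknown.

## Interrupted time series

City-level monthly casualty counts are modelled with a penalized-spline
GAM (via mgcv):

$$\log \mathbb{E}[y_t] = f(t) + g(\mathrm{month}_t) + \log(\mathrm{days}_t)$$

with $f$ a thin-plate regression spline of the month index (basis
dimension 20 by default), $g$ a cyclic cubic spline of month-of-year
(dimension 12, knots at 0.5/12.5 so December joins January smoothly),
and an offset for the number of days per month. Smoothing parameters are
selected by REML, and the fit reports a Pearson dispersion statistic; a
quasi-Poisson family is available when overdispersion is material. The
basis dimensions are defaults, not claims: REML shrinks unneeded
wiggliness, and dimension 20 over two decades of months leaves room for
a slowly varying secular trend.

The counterfactual is a **pre-period sub-model**: the GAM is fitted to
pre-intervention months only and extended over the post months. A 1-D
thin-plate spline extrapolates linearly beyond its training range (its
penalty null space is linear), which is exactly the behaviour wanted for
projecting a secular trend; tests verify that post-period data can be
arbitrarily corrupted without changing the counterfactual. A full-series
fit with an additional smooth of time-since-intervention exists for
plotting, but never feeds the headline comparison — the functional form
of an intervention smooth is under-determined, so inference stays with
the sub-model.

Predicted and observed post-period totals are annualized and compared
with one uncertainty rule throughout: normal approximation on totals
($\mathrm{total} \pm z\sqrt{\mathrm{total}}$, scaled by $1/\text{years}$),
variances added for the difference, and a delta-method CI on the percent
difference $100(\text{pred}-\text{obs})/\text{pred}$ via the ratio of
totals. Published versions of this comparison mix an exact-Poisson
interval into the pre-period row; we apply the one rule everywhere and
note the deviation. The month containing the intervention date counts as
the first post month.

## Exponential speed–injury model

Expected casualty changes from observed speed changes use the
exponential model with severity-specific exponents:

$$\text{pred} = \text{rate}_{\text{before}} \times
  e^{(\bar v_{\text{after}} - \bar v_{\text{before}})\,\beta_s}
  \times \left(1 + \frac{\Delta\text{volume}}{\text{volume}_{\text{before}}}\right)$$

with defaults $\beta_{\text{injury}} = 0.034$ (0.014–0.054) and
$\beta_{\text{serious}} = \beta_{\text{fatal}} = 0.069$ (0.045–0.093)
for the 20–30 mph speed range. The published source of these exponents
does not state their speed unit alongside the mph speeds being analysed;
the exponents' calibration literature works in km/h, so **km/h is the
default exponent unit** and a speed change in mph must be converted
explicitly (`convert_speed()`, exact factor 1.609344). A unit mismatch
is a hard error, never a silent assumption. Both a per-zone-sum path
(`predict_by_zone()`) and an aggregate path are provided; they coincide
exactly when all zones share the same speed and volume changes.

Uncertainty combines the exponent SE, recovered from its 95% bounds as
$(\mathrm{hi}-\mathrm{lo})/2z$, with the Poisson variance of the
before-rate on its count basis: $\mathrm{Var}(\log \text{pred}) \approx
1/N + (\Delta v\,\sigma_\beta)^2$, reported as a first-order normal
interval. Tests check this against Monte-Carlo propagation (agreement
within 3% in the default regime) and against plug-in evaluation at the
exponent bounds. Reproducing the published per-severity predicted values
exactly is out of scope — it requires per-zone speed and volume data
only available in supplementary material — so the model is validated by
its closed-form identities plus a citywide sanity envelope: the
predicted all-casualty rate from the observed 1.3 mph speed drop and 2%
volume drop must fall between the observed pre and post rates (it lands
near 927/year against 1022 pre and 705 post).

## Synthetic data: what it emulates, and what it does not

The generator's defaults are the study conditions, chosen once:

* 36 pre months and 22 post months (3 and 1.83 years);
* 7 implementation/control zone pairs of identical area;
* a secular trend of 0.97/year and log-scale seasonal amplitude 0.1 —
  urban casualty series of this era decline a few percent a year with
  mild summer/winter structure;
* a step intervention rate-ratio of 0.83 (a 17% drop) on converted
  streets from their zone's intervention date, supporting per-zone dates
  (stepped wedge) with a single common date as the default;
* baseline 10 collisions/segment-month (enough events per category for
  stable rates at this network size);
* casualties per collision $= 1 + \text{Poisson}(0.13)$, guaranteeing
  at least one casualty and matching an observed ratio of ~1.13;
* casualty severities drawn as (slight, serious, fatal) =
  (0.85, 0.145, 0.005), the approximate observed mix; the collision
  records the worst casualty;
* Gaussian position jitter with SD 3 m — Gaussian rather than uniform
  precisely so a small tail of points beyond 12 m exercises the
  unmatched path.

The layout is deliberately austere: straight 200 m streets on parallel
rows 40 m apart (so inter-category distances always exceed 30 m and the
12 m rule is unambiguous), implementation zones to the west, their
control twins 1 km east with streets at 30 mph throughout. Ground-truth
segment and zone labels ride alongside every simulated collision for
validating the matcher, and are never visible to the analysis path.

What passing tests on these data do **not** show: real street topology
(curves, junctions, dead ends), spatial correlation of collisions beyond
segment assignment, overdispersion or serial dependence in monthly
counts, reporting artefacts (such as severity reclassification), or
confounding by co-occurring policies. The generator validates the
machinery and the statistical calibration of the estimators under their
own assumptions, not the substantive conclusions.

## Numerical and design choices

* Collision severities are normalized through an explicit alias table,
  case-insensitively; unknown labels are hard errors, never coerced.
* Polygon rings are stored explicitly closed; unclosed input rings are
  auto-closed.
* Degenerate inputs: a zero pre-period count makes the percent change
  undefined (error, or a flagged row in tables); a zero post count
  yields −100% with an undefined SD, flagged.
* All randomness sits behind explicit seeds; the generator restores the
  caller's RNG state.
* Simulation studies in the test suite use 500 replicates of 273-month
  series for the counterfactual calibration, ~11,000 collisions for
  matcher validation, and 10,000 pairs for rate-difference coverage —
  sizes at which Monte-Carlo error is well inside the asserted bands.

## Known limitations

* The DiD assumes independent Poisson count streams: no overdispersion,
  no clustering corrections, no regression adjustment, and no
  multiplicity adjustment across table cells.
* The counterfactual's linear trend extrapolation is trustworthy over a
  couple of years; the package warns beyond a 36-month horizon.
* The Garwood-on-annualized-rate CI inherits the published tables'
  convention; on the raw-count scale the usual Garwood interval on $N$
  scaled by $1/T$ would be narrower for $T > 1$.
* The exponential model treats mean-speed changes as the causal input;
  network-level behaviour change beyond the speed change is exactly what
  it cannot capture, which is the point of comparing it against the
  zone DiD and the interrupted time series.
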