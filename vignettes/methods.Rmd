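---
title: "Estimating elevational range shifts and disentangling their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating elevational range shifts and disentangling their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mountain birds experience two slow environmental pressures at once: climate
warming, which moves their thermal niche upslope, and the encroachment of
shrubs and forest onto abandoned pastures, which erodes open habitat from
below. Both push elevational distributions upward, and because the two
pressures trend together over decades they are badly collinear. `upslope`
implements a pipeline that (i) estimates a species' elevational distribution
independently in every survey year, (ii) tracks landmark points of that
distribution through time, (iii) tests them for upward trends, and (iv)
attributes significant movements to temperature versus habitat by
partitioning the explained variation of each landmark's time series between
the two covariates.

The pipeline is designed for heterogeneous long-term point-count data:
yearly surveys whose locations and sampling effort change from year to year,
with entire gap years. Presence/absence at surveyed points is the only
biological input.

## Yearly response curves and their reference points

For one species and one year, presence at survey points is modelled with a
binomial generalized additive model with logit link,

$$\operatorname{logit} P(\text{presence}) = f(\text{elevation}) +
g(\text{easting}, \text{northing}),$$

where both $f$ and $g$ are penalized thin plate regression splines. The
elevation smooth is capped at 3 effective degrees of freedom so the fitted
curve can only be unimodal or monotone — more flexibility would let sampling
noise manufacture spurious multi-modal "ranges". The spatial smooth, which
absorbs broad spatial autocorrelation, is capped at 15 effective df. Fitting
is delegated to `mgcv`; the df ceilings are enforced through the basis
dimensions (`k = 4` and `k = 16`).

The presence-probability *curve* is the model's prediction along an
elevation grid (default 1 m steps over the surveyed window, 600–2700 m asl)
with the spatial term held at its average over that year's survey locations.
The model never says where along the gradient predictions should be taken;
averaging the spatial surface over the actual sampling locations makes
curves comparable across years with different spatial coverage, and makes
the curve invariant to translating the coordinate system.

Five reference points summarise a curve: the optimum `OPT` (elevation of the
interior maximum $p_{max}$), central borders `CBL`/`CBR` where the curve
falls to $p_{max}e^{-0.5}$, and outer borders `OBL`/`OBR` where it falls to
$p_{max}e^{-2}$. Crossings are located by linear interpolation between grid
points. Because the survey window is bounded, curves are routinely
*truncated*: a landmark whose defining feature lies at or beyond the window
is reported missing rather than extrapolated. When the maximum itself sits
within one grid step of a window edge the curve is monotone over the window,
so the optimum and that side's landmarks are all treated as truncated.
Probability ties at the maximum are broken toward the lowest elevation.

### Bootstrap reliability

Reference points from a single year's fit can be artefacts of sparse data.
Each species × year's rows are therefore resampled with replacement 200
times (`n_boot`), the curve refit and landmarks re-extracted; a landmark is
*reliable* when the refit converged and the landmark fell inside the window
in at least 50% of replicates. The reported elevation is always the
full-data fit, not a bootstrap aggregate — the bootstrap only gates
reliability. "Success" is defined as convergence *and* an in-window
landmark, the strictest reading consistent with truncation.

By default bootstrap refits reuse the full-data fit's spline bases and
smoothing parameters and re-estimate only the coefficients (penalized IRLS
on the resampled rows of the precomputed model matrix). Re-selecting
smoothness inside every bootstrap replicate mostly re-learns the same
penalty from slightly perturbed data at ~25× the cost; holding it fixed is
the usual smoothing-bootstrap compromise. `refit_sp = "free"` restores full
re-selection for users who want it.

A landmark's time series keeps only reliable years, and enters the long-term
analysis only when it has at least 10 reliable years (`min_years`).

## Covariate series

Each reference-point series defines an *elevational belt* — the [min, max]
of the elevations it occupied — over which both covariates are aggregated.
(A per-species belt option exists; per-reference-point is the default and
the two are never silently merged.)

* **Temperature (`tn`)**: daily minimum temperatures on a coarse grid are
  downscaled to the fine terrain grid by the climatology-delta (anomaly)
  method: fine value = fine climatology + (coarse daily − coarse
  climatology) of the enclosing coarse cell. The yearly covariate is the
  mean over all May 1 – June 30 days and all fine cells whose center
  elevation lies in the belt (inclusive bounds) — the breeding-season window
  that drives settlement decisions. Only that window is ever generated or
  used.
* **Habitat (`SF`)**: shrub+forest cover is surveyed only in sparse
  cartography years, so the yearly series is interpolated by a penalized
  spline on year with at most 4 effective df (and never more than the
  number of surveys allows), floored at zero.

## Trend tests and pattern classification

Each informative series is tested with weighted least squares of elevation
on calendar year, weighting each year by its sampling effort $n_y$ — years
estimated from more points are more trustworthy, and under the assumption
that landmark noise variance scales like $1/n_y$ the weights are the
efficient choice. Significance is $p \le 0.05$, two-sided, on $n-2$ df.
Temporal autocorrelation is measured with the Durbin–Watson statistic but
deliberately not corrected: both the response and the covariates trend, so
the autocorrelation is largely shared, and correcting it would also discard
real signal. The statistic is reported as a flag only.

Species patterns follow from which landmarks moved: both extremes moving at
significantly different rates implies contraction (lower steeper) or
expansion (upper steeper); equal rates imply a coherent shift; one extreme
alone implies its boundary's contraction/expansion; central landmarks alone
imply a shift. The extreme-slope comparison is a two-sided z test on the
slope difference of the two independent fits — the simplest defensible
choice, and configurable, since no canonical test exists for this
comparison. For the packaged reference table, which prints no standard
errors, the comparison outcome is shipped as printed data.

## Driver attribution

For each significant landmark, elevation is regressed on `tn` and `SF`
(weighted as above), and the explained variation is decomposed from the
three nested weighted models ($R^2_{tn}$, $R^2_{SF}$, $R^2_{both}$) into

* net temperature: $R^2_{both} - R^2_{SF}$,
* net habitat: $R^2_{both} - R^2_{tn}$,
* shared: $R^2_{tn} + R^2_{SF} - R^2_{both}$,
* unexplained: $1 - R^2_{both}$,

with negative components floored at zero and the discrepancy folded into the
shared fraction, so the four always sum to one. This unique/shared reading
of "contributed deviance" is the only one under which the four fractions are
additive; the classical averaged-order independent-effects decomposition
(each unique effect plus half the shared) is also provided
(`independent_effects()`) but cannot express a large shared column and is
not the default.

Driver classes follow threshold rules in order: shared > 0.9 ⇒ *nd* (not
distinguishable); both nets ≥ 0.1 ⇒ *tn+SF*; net SF ≥ 0.1 ⇒ *SF*; net tn ≥
0.1 ⇒ *tn*; unexplained > 0.9 ⇒ *none*; otherwise *nd* via fallback. Two
resolution steps then use the regression evidence:

1. an *nd* whose temperature coefficient is individually significant while
   the cover coefficient is not becomes *tn* — under strong collinearity the
   partition cannot separate the drivers, but a lone significant coefficient
   can;
2. a *fallback* *nd* (nothing crossed a threshold) with at least one
   individually significant coefficient becomes the significant driver with
   the larger net contribution. This codifies decisions that in the
   reference study appear to have been made case by case; restricting step 1
   to temperature-only significance and step 2 to fallback rows reproduces
   every published call without touching any other row.

Finally, an upper landmark (CBR/OBR) with a *negative* cover coefficient and
a final class of *SF* or *nd* is relabelled a density-dependent effect,
`dde(SF)`/`dde(nd)`: cover declines with elevation, so a negative
coefficient at an upper boundary is ecologically spurious and is read as
spillover of dense lower populations into suboptimal higher habitat.

## Association analysis

Patterns, breeding habitat (open/edge/forest), migration habit
(ldm/sdm/res) and driver (tn/SF/tn+SF/nd/dde — the dde relabels form one
level) are crossed into a complete 3×3×3×5 = 135-cell contingency table and
analysed with sequential Poisson log-linear models: the four main effects,
then the three pattern interactions, each row reporting the deviance drop
and a chi-squared p-value. Zero cells are handled natively by the Poisson
likelihood; no continuity corrections. Because a species has one pattern but
possibly several driver calls, the counting unit is configurable — one
record per species × distinct driver class (default) or one per significant
reference point; published analyses of this design do not pin the unit down,
so exact published deviances are not a validation target (the table
*structure* is: 134 null residual df, telescoping drops, saturated deviance
zero).

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions the pipeline was built for:
28 survey years spanning 1982–2017 with the historical gap years, a
600–2700 m window, yearly effort drawn from 67–782 points, a warming trend
of 0.046 °C/yr on May–June daily minima (about 0.46 °C/decade), and
shrub+forest cover growing 4140 → 4364 km² (1980–2015) with ~85% of the
gain below 1200 m. Species are split Gaussians on elevation — lower- and
upper-side scales may differ and may drift separately, so one-sided boundary
dynamics exist by construction — with analytic reference points
(μ ± σ·side, μ ± 2σ·side) available as ground truth.

Not emulated: within-territory spatial autocorrelation of presences
(points are independent Bernoulli draws), observer and detection effects
(the emulated surveys cannot separate detection from presence either),
abundance. Passing tests therefore demonstrate correct estimation under
independent, perfectly detected presences; they cannot certify behaviour
under strong detection artefacts.

## Numerical choices and problem sizes

* Prediction grid step 1 m by default; simulation-heavy tests use 5 m,
  which bounds landmark discretisation error at 5 m against effects of
  hundreds of meters.
* Spline bases: thin plate; the spatial basis uses knot thinning
  (`max.knots = 60`) — a standard cost control that leaves the df ceiling
  untouched.
* Bootstrap refits: fixed smoothing parameters (see above);
  non-convergent replicates count as failures, they are never retried.
* The packaged validation suite runs the replicate-recovery experiment at
  50 worlds × 28 years × 50 bootstrap replicates with 300 points/year, and
  the null-size experiment at 1000 weighted regressions; both recover their
  targets (CI coverage of the true drift; nominal test size).
* Seeds are explicit everywhere; stage seeds are derived deterministically
  from one master seed and kept below $2^{31}$.

## Known limitations

* The reference-point estimator inherits GAM boundary bias: optima within a
  grid step of the window edge are unidentifiable and are reported
  truncated rather than estimated.
* Variation partitioning with two strongly collinear predictors has low
  power to separate them — that is precisely why the *nd* class and the
  resolution rules exist, and why large shared fractions dominate realistic
  runs.
* The weighted trend test assumes landmark noise variance inversely
  proportional to effort; gross violations would distort its size.
* Exact reproduction of published log-linear deviance values is out of
  scope (counting unit under-specified); the package validates structure
  and its own arithmetic instead.
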