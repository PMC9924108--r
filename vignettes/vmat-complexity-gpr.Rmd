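---
title: "Modulation complexity and gamma-passing-rate prediction for VMAT plans"
author: "vmatQA"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Modulation complexity and gamma-passing-rate prediction for VMAT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatQA)
```

## The problem

Volumetric-modulated arc therapy (VMAT) delivers dose while the gantry
rotates, with the multileaf collimator (MLC), dose rate and gantry speed
all changing between control points.  Heavily modulated plans are harder
to calculate and to deliver accurately, and pretreatment verification
measures this as a gamma passing rate (GPR): the fraction of measurement
points passing a combined dose-difference / distance-to-agreement test
(here 3 %/2 mm with a 10 % low-dose threshold).  Physicists would like to
know, *before* measuring, whether a plan's geometry makes a low GPR
likely.  `vmatQA` implements that workflow: plan-geometry complexity
metrics, regression of GPR on those metrics, and percent-error checking
of delivered machine parameters, together with a synthetic cohort
generator so that the entire pipeline is testable end to end without
clinical data.

## Complexity metrics

All geometry is in IEC 61217 coordinates, mm at isocenter.  At each
control point the aperture is the union of per-leaf-pair rectangles: the
open x interval of pair $i$ is $[\max(A_i, x_1), \min(B_i, x_2)]$ (bank A
is the X1 side) and its y extent is the leaf span clipped to the Y jaws.
Pairs whose clipped gap is at or below the machine's `minGap`
(default 0.5 mm, the usual dynamic-leaf-gap convention for "closed"
pairs) are dropped.

From the aperture shape the per-control-point quantities are

* **AA**, aperture area (mm^2): the summed area of the retained
  rectangles;
* **AP**, aperture perimeter (mm): the boundary length of their union.
  Adjacent pairs sharing part of their x interval merge; a closed pair
  between open ones splits the opening into separate polygons, each
  contributing its own boundary;
* **AI**, aperture irregularity: the isoperimetric ratio
  $AP^2 / (4 \pi \, AA)$, equal to 1 for a circle and at least $4/\pi$
  for any rectilinear aperture (equality only for a single square).

Per beam, **BA** and **BI** are the MU-weighted means of AA and AI over
the arc.  The weight of a control point is the meterset delivered in the
segment that *follows* it, so the final control point carries no weight;
this interval convention is one of several defensible choices and is
pinned by the constant-aperture identity (a beam whose aperture never
changes has BA = AA and BI = AI under any weighting).  BI is the weighted
mean of per-control-point AI, not the AI of an averaged shape, following
the convention of the metric's source literature.  Control points whose
aperture is fully closed have no defined AI; they are excluded from the
BI average together with their weight.

Per plan, **PA** and **PI** average BA and BI over beams with beam MU as
weights.  The remaining plan-level features are

* **total MU**;
* **LT/AL** (mm/deg): mean leaf travel divided by arc length.  A leaf
  participates in the average when its pair is ever open (after jaw
  clipping) during the beam, and both banks are counted individually.
  The alternative of averaging over all 120 leaves is available via
  `participation = "all"`; the default restricts to ever-open pairs
  because leaves parked behind the jaws never shape the field.
* **DR variation** ((MU/min)/deg) and **GS variation** ((deg/s)/deg):
  summed absolute changes of segment dose rate and gantry speed divided
  by arc length, MU-weighted over beams like PA/PI (the multi-arc
  aggregation is not fixed by the source description; mirroring the
  PA/PI rule keeps all six features on the same footing).

### Reconstructed delivery dynamics

RT Plans store neither dose rate nor gantry speed.  They are
reconstructed per segment with the standard maximum-constraint model:
the segment duration is set by whichever axis limits,
$\Delta t = \max(\Delta MU / DR_{\max},\; \Delta\theta / GS_{\max})$,
giving $DR = \Delta MU/\Delta t$ and $GS = \Delta\theta/\Delta t$.  One
of the two constraints is always active, so a beam whose every segment
is MU-limited delivers at constant (maximum) dose rate and has zero DR
variation, while its gantry speed modulates — and vice versa.  Machine
limits default to $GS_{\max} = 4.8$ deg/s and a dose-rate ceiling
resolved from the beam energy label (600 MU/min flattened, 1400 for
6FFF, 2400 for 10FFF); these are typical C-arm linac values, are not
dictated by the analysis being reproduced, and are overridable in
`machineModel()`.  Gantry angles are unwrapped across the 0/360 seam by
taking each step on the shortest path, which is unambiguous at VMAT
control-point spacing (about 2 degrees); variation sums run over
consecutive derived segments.

## The synthetic cohort generator

No clinical plans ship with the package; `generatePlan()` draws plans
from four site archetypes whose complexity structure mirrors what a
mixed clinical VMAT cohort looks like:

| archetype | arcs | aperture scale | irregularity | modulation | MU range | MU burstiness | energy |
|---|---|---|---|---|---|---|---|
| IMRS (radiosurgery) | 6 | 7 mm | high | high | 1800–3400 | high | 6FFF |
| HN (head & neck) | 2 | 16 mm | high | high | 450–780 | medium | 6FFF |
| MED_LUNG | 2 (220° arcs) | 20 mm | medium | medium | 600–2200 | medium | 6FFF |
| PROSTATE | 1 | 27 mm | low | low | 560–720 | low | 10MV |

Each arc's leaf openings trace the chords of a slowly rotating ellipse,
perturbed by a static per-leaf boundary noise (`irregularity_level`, mm)
and by AR(1)-smoothed control-point-to-control-point jitter
(`modulation_level`, mm); meterset increments follow a gamma
distribution whose shape sets how bursty the delivery is.  Both noise
levels also vary plan-to-plan around the archetype value, giving
within-site spread.  The archetypes reproduce the qualitative cross-site
ordering of the metrics — radiosurgery plans have the smallest
plan-averaged beam area and the highest irregularity, prostate plans the
largest area, lowest irregularity and least total-MU variability — and,
through the energy/MU interplay of the delivery model, put prostate
plans in the MU-limited regime (dose rate pinned at its ceiling, gantry
speed modulating) and radiosurgery plans in the gantry-limited regime.

Simulated GPR is a *clipped linear-Gaussian response*:
$\mathrm{GPR} = \mathrm{clip}(\beta_0 + \sum_j \beta_j z_j +
\varepsilon,\; 80,\; 100)$, with $z_j$ the cohort-standardized features
and $\varepsilon \sim N(0, \sigma)$, $\sigma = 1$ GPR point by default.
This is the simplest structure consistent with the linear correlations
reported for clinical cohorts and with the adequacy of a linear SVR; it
is a calibration device, not a physical model, and its coefficients have
no physical meaning.  The default coefficients were calibrated once
against a large reference cohort so that the empirical feature–GPR
Pearson correlations of a default cohort land on the clinical pattern
(about +0.72 for PA, −0.67 PI, −0.66 total MU, +0.62 GS variation,
−0.50 DR variation, −0.38 LT/AL).  Because the six features are strongly
inter-correlated across sites, most of PA's marginal correlation arrives
through the cohort covariance structure rather than through a large
direct weight; the direct weights keep the conventional sign pattern
(positive PA and GS variation, negative elsewhere).  The intercept
(95.5 %) and noise put ≥ 90 % of simulated GPRs in (90, 100], the band
where measured passing rates concentrate; the hard clip at 100 encodes
that a passing rate cannot exceed 100 %.

What the generator does *not* emulate: dose calculation, detector
geometry and the gamma computation itself (GPR is simulated, never
computed from dose); leaf-speed and interdigitation constraints;
couch/collimator rotation; anatomical realism.  Tests passing on
synthetic cohorts therefore validate the *pipeline machinery* — metric
definitions, model plumbing, evaluation protocol — not clinical
predictive performance.

## GPR regression

Two regressors are provided with the hyperparameters pinned by the
reference analysis: a random forest (150 trees, at least 6 samples per
leaf, sqrt-of-p candidate features per split) and a support-vector
regression with linear kernel, $C = 1$, $\epsilon = 0.5$.  The R random
forest does not expose a minimum-samples-per-split or an explicit depth
cap; with 6 samples required per leaf on cohorts of a few hundred plans,
trees cannot approach the nominal depth cap of 80, so neither constraint
can bind.  Features are z-scored with training statistics before the SVR
(which is scale-sensitive at fixed C); the forest consumes raw features.

### The logit rescaling

Measured GPRs concentrate just below 100 %, and an unbounded regressor
fitted to raw percentages can predict above 100 %.  Targets for the SVR
are therefore rescaled: divide by 100, subtract 0.9 (negative results
floored at zero), multiply by 10, then apply the logit.  Predictions map
back through the inverse logit, which confines them to (90, 100) — no
prediction can exceed 100 %.  The floor-at-zero rule makes logit(0)
undefined, so the logit argument is clipped to
$[\epsilon, 1 - \epsilon]$ with $\epsilon = 10^{-3}$; this
regularization is required for well-posedness and bounds the transform's
image away from the singularities.  The forward/inverse pair is an exact
bijection on the open band $(90 + 100\epsilon/s,\; 100 - 100\epsilon/s)$.

By default the rescaling applies to the SVR only: the forest averages
training targets and cannot extrapolate beyond 100 on its own.
`applyTo = "both"` transforms both models; `applyTo = "none"` fits both
on raw percentages.  The `"none"` setting exists for recovery
diagnostics: when a synthetic response is linear *on the percent scale*,
the rescaled target is curved (and plans clipped at exactly 100 map to a
large constant), so no linear model in logit space can recover it
perfectly — on such cohorts raw-target SVR reaches test $R^2 \ge 0.98$
while the default rescaled pipeline plateaus around 0.95 in exchange for
guaranteed boundedness.  Both behaviors are asserted in the test suite.

### Evaluation protocol

`repeatedHoldoutEval()` repeats a 70/30 split (30 times by default, all
driven by one master seed, so the full summary is bit-reproducible):
fit on the training fraction, score held-out plans by absolute error in
GPR percentage points, and summarize MAE, RMSE and $R^2$ as mean ± SD
across repeats.  $R^2$ is computed per test split, not pooled, matching
the mean-±-SD presentation convention of the reference analysis; RMSE ≥
MAE on every repeat by the power-mean inequality, which the tests
assert.  The summary also reports the overall maximum absolute error and
the fraction of held-out predictions within a 3 % threshold.
`permutationImportance()` measures the mean decrease in test-set $R^2$
over independent within-column permutations — model-agnostic, applied
identically to both regressors.

Correlation reporting uses Pearson's r with two-sided p-values and the
conventional strength labels on |r|: none (≤ 0.2), weak (≤ 0.4),
moderate (≤ 0.6), strong (≤ 0.8), very strong (> 0.8).  The published
category boundaries leave gaps (e.g. 0.205 belongs to no stated
interval); half-open intervals assign each boundary to the lower
category.  Cross-site differences in the metrics are tested with
classical one-way (equal-variance) ANOVA per metric.

## Delivery-log checking

`percentError()` implements the standard check of delivered against
planned machine parameters,
$(\mathrm{actual} - \mathrm{expected})/\mathrm{expected} \times 100$,
on tabular expected/actual series (binary trajectory-log parsing is out
of scope; logs are supplied as CSV-like tables).  The ratio is undefined
at a zero reference — a gantry at 0°, a jaw at 0 mm — and such samples
are reported as undefined and excluded from maxima rather than silently
zeroed, because no unambiguous convention exists.  Angle series should
be unwrapped (`unwrapAngles()`) first so the 0/360 seam does not
register as a spurious error.  `compareDelivery()` reports, per
parameter and optionally per site, the maximum absolute percent error
with the sample index that achieves it.

## Numerical and design choices, in brief

* Closed-pair threshold `minGap` 0.5 mm; pairs at or below it are
  treated as closed everywhere.
* Cumulative meterset weights are normalized to a final value of 1
  (DICOM convention); segment MU = Δweight × beam MU.
* Plans failing an invariant are reported by `validatePlan()` as a
  character vector naming beam, control point and rule — violations are
  data, not exceptions, so broken plans can be diagnosed.
* DICOM reading covers little-endian implicit and explicit VR RT Plans
  with positions carried forward across control points; beams without a
  positive meterset (setup fields) are skipped, and leaf-count
  mismatches against the machine profile are hard errors.
* Static-gantry beams have zero arc length; every per-degree metric
  refuses them explicitly rather than dividing by zero.
* Test problem sizes: oracle comparisons run 1000 random apertures per
  MLC profile against an exhaustive grid-aligned rasterization oracle;
  calibration and noise-floor checks use 500-plan cohorts; recovery
  checks 150–200 plans.  These sizes were chosen to make the checked
  statistics stable at the asserted tolerances.

## Limitations

The regression quality figures obtainable here describe synthetic
cohorts whose response model is known and linear; clinical GPR depends
on machine performance, detector setup and dose calculation in ways no
plan-geometry metric captures.  The generator's archetypes encode one
clinic's qualitative site structure; transferring the fitted models to
real data requires retraining on measured GPRs.  Only Varian-style
60-pair MLC geometries are built in, and only the six plan-level
features are computed (other indices from the literature — MCS, edge
metric — carry similar information and are deliberately omitted).
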