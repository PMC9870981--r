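---
title: "Quantifying the endothelial glycocalyx from intravital microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the endothelial glycocalyx from intravital microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxi)
```

## The measurement problem

The endothelial glycocalyx is a carbohydrate-rich gel coating the luminal
surface of blood vessels. It regulates vascular permeability and is degraded
in hemorrhagic shock; how quickly it degrades, and whether resuscitation
fluids protect it, are questions studied by intravital fluorescence
microscopy. A lectin stain (FITC-WGA) illuminates the vessel wall, so that a
line drawn perpendicular to the wall shows a bright intensity peak whose
width is an operational score of glycocalyx-layer thickness — the
*glycocalyx index* (GCXI). Separately, vascular permeability is scored by
tracking labeled tracers (TMR-DEX40, FITC-HES130) as they leak from the
lumen into interstitial tissue over tens of minutes.

This package implements that quantification end to end: profile extraction
from annotated wall traces, the width-at-fractional-height GCXI algorithm,
interstitial region-of-interest (ROI) time courses, the group-level
inference layer (one-way ANOVA with Dunnett many-to-one comparisons and
Kaplan–Meier/log-rank survival), and a synthetic-scene generator that makes
every stage verifiable against known ground truth.

## The GCXI algorithm

For one wall profile $I(x)$ sampled along the perpendicular (position $x$ in
pixels, negative toward the lumen):

1. Optionally smooth $I$ with a Savitzky–Golay local polynomial filter.
2. The peak $a$ is the global maximum of the smoothed profile (ties broken
   toward the smaller position).
3. One inflection point is located on each flank. The search is anchored at
   the flank's steepest point — the extremum of the central-difference first
   derivative — and the inflection is the second-derivative zero crossing
   bracketing that extremum, interpolated linearly to sub-sample precision.
4. The baseline is $c = \tfrac12\,[I(x_L) + I(x_R)]$, the mean of the two
   inflection-point intensities.
5. The measurement level is the lower boundary of the upper 40 % of the
   peak-above-baseline range, $b = c + (1 - f)(a - c)$ with $f = 0.40$.
6. The width $d$ (the GCXI of that line) is the distance between the
   level-$b$ crossings nearest the peak on either side, again located by
   linear interpolation between samples.

Three perpendicular lines are placed 50 px apart, centred on the annotated
wall segment (so that three lines divide it into four blocks), and the GCXI
of an artery is the arithmetic mean of its three line widths. Arteries with
fewer than three usable lines are excluded and logged with a reason code,
though `require_three = FALSE` permits fewer-line averages.

Two closed forms anchor the implementation. For a Gaussian ridge of scale
$\sigma$ the inflections sit at $\pm\sigma$, $c = a\,e^{-1/2}$, and

$$d = 2\sigma\sqrt{-2\ln(0.6 + 0.4\,e^{-1/2})} \approx 1.17048\,\sigma ,$$

while a raised-cosine ridge of half-width $w$ gives
$d = (2w/\pi)\arccos(0.6) \approx 0.5903\,w$. These are frozen as analytic
oracles in the test suite and the width converges to them as the sampling
step shrinks (within 0.5 % at a 0.1-px step). The construction also makes
$d$ invariant under affine intensity maps $I \mapsto \alpha I + \beta$
($\alpha > 0$), equivariant under spatial rescaling, and symmetric under
profile reflection, each of which is tested on randomized profiles.

### Why the inflection search is anchored at the steepest point

The textbook rule — take the second-derivative zero crossing *nearest the
peak* — is exact on noiseless unimodal ridges but brittle in practice: with
photon and read noise at a signal-to-noise ratio around 10, the second
derivative of even a heavily smoothed profile flips sign repeatedly near the
crest, and the nearest crossing collapses the baseline onto the peak,
shrinking measured widths toward zero. Anchoring the search at each flank's
first-derivative extremum selects the *principal* inflection — the one
carrying the flank — and reduces to the nearest-crossing rule on clean
profiles (on a Gaussian both rules give $\pm\sigma$ exactly). The
Savitzky–Golay end transient (half a window at each profile end) is excluded
from the search; profiles whose steepest point falls at the search boundary
are rejected as unusable rather than silently mismeasured.

### Parameters that matter

* `upper_fraction` (default 0.40, dimensionless): the "upper 40 %" band.
  The level $b$ sits at 60 % of the peak-above-baseline range; setting the
  fraction differently supports the alternative width-at-40 %-height
  reading.
* `smoothing_window` / `smoothing_polyorder` (samples / degree, defaults
  7 / 3): light smoothing suited to mildly noisy acquisitions, and the
  window is configurable because it should scale with noise: for SNR ≈ 10
  acquisitions we use 35 samples (at the 0.5-px default step, a span of
  about 17 px — roughly the width of the peaks being measured). Window 1
  disables smoothing; analytic and noiseless tests run unsmoothed.
* `half_length_px` / `n_samples` (defaults 25 / 101, i.e. 0.5-px steps):
  the profile must extend past the layer's inflection points, so for layers
  up to ~6 µm at 0.25 µm/px (inflections at ±24 px) we extend to
  `half_length_px = 40`. Sub-pixel sampling with bilinear interpolation is
  what makes sub-pixel width estimates meaningful.
* `pixel_scale` (µm/px, default 1): the microscope calibration; widths are
  computed in pixels and converted to microns only at reporting.

## Permeability time courses

Three 80 × 80-px square ROIs are placed by seeded rejection sampling
(budget 10 000 attempts) so that they contain no vessel pixel and are
pairwise disjoint; infeasible placement is an error, never a silent retry
with fewer ROIs. The reported interstitial intensity per channel and time
point is the arithmetic mean of the three ROI means, measured at 15, 30, 60
and 90 min with the same ROI set reused across time points (re-drawing per
time point is possible by re-selecting with a different seed). The exporter
reports both raw and baseline-normalized (divided by the 15-min value)
series, since published time courses are often relative.

## Inference layer

Endpoint tables are compared by one-way ANOVA followed by Dunnett's
two-sided many-to-one test against the control group, both computed from
`(mean, SD, n)` summaries — algebraically identical to the raw-data
versions, which lets printed tables be re-analysed directly. For treatment
$i$ versus control $0$,

$$t_i = \frac{\bar y_i - \bar y_0}{\sqrt{\mathrm{MSE}\,(1/n_i + 1/n_0)}},
\qquad
p_i = P\!\left(\max_j |T_j| \ge |t_i|\right),$$

where $(T_1,\dots,T_k)$ follow the multivariate $t$ distribution with
$N - k$ degrees of freedom and correlations $\lambda_i\lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i + n_0)}$. The tail probability is evaluated by
a deterministic tensor-product quadrature (Gauss–Hermite in the shared
normal factor, Gauss–Legendre in the probability transform of the pooled
scale), accurate to about $10^{-5}$ — verified in the tests against a
$10^6$-draw Monte-Carlo max-$|T|$ oracle and against an independent
multivariate-$t$ integrator. Equal-variance pooling is used even for
visibly heteroscedastic endpoints because that is what ANOVA + Dunnett
assumes and what the published tables report; significance flags follow the
tables' convention (`*` for $p \le 0.05$, `**` for $p \le 0.01$). The
statistical unit follows the source tables (vessels for the GCXI rows,
animals elsewhere); no mixed-effects correction is attempted.

Re-deriving the comparisons from the printed summaries reproduces every
published flag except two: the 60-µm GCXI comparisons for NS-NS and NS-ALB,
marked `*` in the source, compute to adjusted $p \approx 0.09$–$0.11$ under
a two-sided test on the rounded summaries. Those two marks are not
reproducible from the published numbers alone (a one-sided test or
per-line rather than per-artery units would be required), and the test
suite asserts only the wide-margin contrasts ($|t|$ between 3.7 and 6.3),
all of which reproduce at $p \le 0.01$.

Survival is handled with the standard Kaplan–Meier product-limit estimator
and the log-rank test (via the survival package), checked against
hand-computed product limits, a hand hypergeometric tally, and a
label-permutation reference.

## The synthetic generator

`vessel_scene()` renders one straight artery per frame: a bright wall ridge
of known cross-section (Gaussian of scale σ, or raised cosine of half-width
w, in µm) on both sides of a lumen plateau, with the crest polyline, vessel
mask, analytic expected width, and leakage ground truth returned alongside
the frame. Tracer channels take their interstitial level from the
single-compartment law $I(t) = I_0 + I_{\max}(1 - e^{-kt})$. Noise follows
the standard photon/read decomposition — Poisson first (signal-dependent,
`poisson_gain` photons per intensity unit), then additive Gaussian — and is
bit-reproducible under a seed. Intensities stay floating point throughout;
quantization to 16 bits happens only at TIFF export, with the scale factor
recorded in the JSON sidecar.

Default study conditions: arteries of 40 or 60 µm inner diameter, layer
scales of 2–6 µm, observation times 15/30/60/90 min, endpoint cohorts drawn
from the published per-group `(mean, SD, n)` rows
(`study_endpoint_summaries()`), and seven-day survival with exponential
event times from per-group constant weekly death probabilities. The weekly
death probabilities default to a neutral 0.5 because the published per-group
mortality numbers are internally inconsistent (the text's survival/mortality
wording appears inverted) and the per-group records are not machine-readable;
the simulator therefore treats hazards as free parameters. The default
pixel scale is 1 µm/px (no calibration is published; recovery experiments
here use 0.25 µm/px so that sub-pixel effects are exercised).

What the generator does *not* emulate — optical point-spread blur, breathing
and motion artifacts, vessel curvature, red-blood-cell flow, multi-vessel
networks — bounds what passing tests show: they demonstrate that the
algorithms are correct and stable under realistic photon statistics on the
geometry the measurement was designed for (straight, non-overlapping
arteries), not that the pipeline segments or registers difficult real
scenes. Wall traces are supplied by the user (or by ground truth);
automated vessel detection is out of scope.

## Numerical choices and degenerate inputs

* Peak ties break toward the smaller position; all sub-sample positions
  come from linear interpolation (of the second derivative for inflections,
  of the profile for level crossings).
* Multiple level-$b$ crossings (noisy shoulders): the crossings nearest the
  peak are used, measuring the peak itself rather than distal structure.
* Flat or monotone profiles, missing flank inflections, and uncrossed
  measurement levels raise distinct error classes (`gcxi_no_peak`,
  `gcxi_no_inflection`, `gcxi_no_crossing`) so that callers drop the line
  and log the reason; the pipeline records every exclusion in its run log.
* ANOVA on groups that are all constant and equal is an error (F is
  undefined), not `NaN`.
* The simulate–measure–infer pipeline derives per-artery seeds from the
  config seed, so a run is reproducible byte-for-byte; CSV floats are
  written with 9 significant digits.

## Problem sizes used in the checks

The verification experiments are sized for a laptop: 512 × 512-px scenes at
0.25 µm/px, 50 noisy replicates per layer scale, $10^6$ Monte-Carlo draws
per Dunnett oracle configuration, 2 000 null replicates for the familywise
error rate, and 1 000-case randomized invariance sweeps. The full test
suite runs in under two minutes.

## Known limitations

The GCXI is an operational index, not an absolute thickness: it depends on
the stain, the optics and the band fraction, and the package makes no claim
beyond the published 4–6 µm scale context. Inference from printed summaries
inherits their rounding; two published significance marks are not
recoverable from them (above). The permeability layer reports mean ROI
intensities, not permeability coefficients — no pharmacokinetic fitting,
background subtraction or photobleaching correction is attempted.
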