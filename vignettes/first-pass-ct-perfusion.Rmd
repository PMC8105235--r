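---
title: "Two-volume first-pass CT myocardial perfusion: model, phantom and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-volume first-pass CT myocardial perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpact)
```

## The measurement model

Dynamic contrast-enhanced CT can quantify myocardial perfusion because
iodinated contrast raises tissue attenuation in proportion to its local
concentration.  During the first pass of a bolus -- before any appreciable
venous outflow -- the myocardium behaves as a single inflow-only
compartment: contrast mass accumulates at a rate equal to perfusion times
the arterial concentration.  Conservation of mass then gives the average
perfusion over the segmented myocardium as

\[
P_{AVE} \;=\; \frac{\Delta HU_{AVE}}{\Delta t \; C_{in} \; \rho},
\qquad
P(v) \;=\; P_{AVE}\,\frac{\Delta HU(v)}{\Delta HU_{AVE}},
\]

where \(\Delta HU\) is the enhancement change of a voxel between two
whole-heart volume scans V1 and V2, \(\Delta HU_{AVE}\) its mask average,
\(\Delta t\) the time between the scans in minutes, \(C_{in}\) the
aortic-root blood-pool enhancement averaged between the two scans (HU above
the pre-contrast baseline), and \(\rho = 1.055\) g/mL the density of
myocardial tissue.  The unknown proportionality constant between HU and
concentration appears in numerator and denominator and cancels, so the
whole computation runs in Hounsfield units.  `compute_perfusion()`
implements exactly this closed form and records every constituent
(\(C_{in}\), \(M_T\), \(\Delta HU_{AVE}\), \(\Delta t\), and the
contrast-entry-rate proxy \(dM_C/dt\)).

Two protocol details matter.  V1 is acquired when the aortic enhancement
first exceeds a trigger threshold (140 HU above baseline by default) on the
bolus-tracking curve; V2 is acquired at approximately the aortic peak,
where it doubles as a CT angiogram if run at diagnostic tube current.
`detect_trigger()` uses a sample-and-hold rule -- the first discrete sample
at or above threshold, no interpolation -- because that is how a scanner's
monitoring scan operates, and it makes oracle tests exact.  Peak ties break
to the earliest sample.  An optional one-frame trigger latency models
scanner arming delay; it defaults to zero.

\(C_{in}\) is baseline-subtracted.  The derivation requires the
contrast-attributable signal, so the measured pre-contrast blood HU is
removed from the two-scan ROI average; the un-subtracted variant is
available (`subtract_baseline = FALSE`) for sensitivity analyses, as is an
ROI erosion radius for a stricter "central" blood-pool sample (default 0).

CFR is the voxel-wise ratio of stress to rest perfusion.  Rest voxels below
a floor (0.1 mL/min/g by default) produce unstable ratios and are flagged
undefined rather than propagated.  Vessel-level CFR is reported as the
ratio of territory mean stress to territory mean rest perfusion -- not the
mean of voxel ratios -- because the ratio of means is the quantity that
remains stable under noise and is the convention for territory tables.

## The digital phantom

All quantitative claims in this package are exercised against a synthetic
4D phantom (`phantom_spec()`, `simulate_acquisition()`) with known ground
truth rather than against scans.  It emulates:

* an LV myocardium as a truncated half-ellipsoid shell (outer minus inner
  ellipsoid, cut above the base plane) on the scanner voxel grid of
  0.43 x 0.43 x 0.5 mm;
* an aortic-root cylinder, geometrically disjoint from the shell, whose
  voxels follow baseline blood HU plus a gamma-variate bolus
  \(C_a(t) = A\,[(t-t_0)/(\alpha\beta)]^{\alpha} e^{\alpha-(t-t_0)/\beta}\),
  parameterised so the peak equals \(A\) at \(t_0 + \alpha\beta\);
* inflow-only tissue uptake: each myocardial voxel's HU at time \(t\) is
  baseline plus \(P_{true}\,\rho \int_0^t C_a\,d\tau\), evaluated with the
  closed-form incomplete-gamma antiderivative (tests confirm agreement with
  fine-grid numerical integration to better than 0.1%);
* three epicardial centerlines (LAD anterior, LCx lateral, RCA inferior)
  lying on the outer shell, with an optional stenosis marker partitioning a
  distal LAD sub-territory;
* stationary Gaussian HU noise scaling with tube current as
  \(\sigma(mA) = \sigma_{ref}\,(mA_{ref}/mA)^{1/2}\), the quantum-noise
  approximation (\(\sigma_{ref} = 25\) HU at 50 mA by default); and
* an optional constant baseline drift per acquisition emulating
  recirculation between repeated injections (default 0).

The default study conditions (`default_swine_spec()`) follow the swine
protocol the method was validated in: one frame per cardiac cycle
(0.72 s at ~83 bpm), rest territory flows of 0.58/0.53/0.37 mL/min/g
(LAD/LCx/RCA), stress flows of 2.07/2.15/1.79 mL/min/g, and a stenosed
distal LAD sub-territory at 1.20 mL/min/g stress.  The distal rest flow is
not separately tabulated in the source data; 0.67 mL/min/g is used so the
implied distal CFR (1.20/0.67 = 1.8) matches the reported stenotic CFR.

### Choosing the bolus parameters

The bolus shape is the one genuinely open configuration choice.  Three
constraints act on it: the trigger-to-peak delay must fall in the
physiologically observed 4.10--8.93 s window; the acquisition samples once
per cardiac cycle; and the two-volume estimator itself, which approximates
\(\int_{t_1}^{t_2} C_a\,d\tau\) by the two-point trapezoid
\(\Delta t \cdot (C_a(t_1)+C_a(t_2))/2\), should operate in its
small-curvature regime where that approximation is good.  A numerical scan
of the gamma-variate family shows the trapezoid bias grows with peak
enhancement (the trigger then sits lower on the convex toe of the upslope):
at a 400-HU peak the bias exceeds 8% for every in-window delay, while a
dilute bolus with \(A = 200\) HU, \(\alpha = 8\), \(\beta = 2.8\) s,
\(t_0 = 6\) s yields a 5.04 s sampled delay and a +3.9% bias.  The default
therefore models a dilute, slowly infused injection.  This is a property of
the estimator worth knowing in practice: with steep, concentrated boluses
the two-point input average underestimates the true integrated input, and
perfusion is correspondingly overestimated -- by roughly 4% under the
default conditions, cancelling exactly in CFR since rest and stress share
the input shape.

The `linear_ramp` input mode replaces the gamma-variate by a linear
enhancement ramp, for which the two-point trapezoid is exact; it isolates
the estimator's discretisation error from its model error and is used by
the exactness-limit tests (recovery to float precision).

### What the phantom does not model

Beam hardening, streak/metal artifacts, cardiac and respiratory motion,
ECG gating, projection-domain physics, contrast outflow and recirculation
shape, and realistic four-chamber anatomy are all out of scope.  Passing
phantom tests therefore demonstrates the correctness of the computational
pipeline under its stated model -- not robustness to scanner physics or
segmentation error on real data.

## Territory assignment

Each myocardial voxel is assigned to the coronary tree reachable at least
path cost.  Centerlines are resampled at half-voxel intervals, snapped to
voxel centers, and used as multi-source seeds for a Dijkstra computation on
the 26-connected voxel graph with Euclidean edge lengths in mm.  Paths are
restricted to the myocardium plus a straight corridor joining each seed to
its nearest myocardial voxel -- the epicardial centerlines lie just outside
the segmented muscle, and the corridor gives them a metric-faithful entry
point without letting paths shortcut through free space.  The cited
assignment literature does not publish its exact cost function; this
Euclidean-geodesic interpretation is the canonical one, and the engine is
isolated behind `assign_territories()` so alternative costs can be swapped.
Ties break in the fixed order LAD < LCx < RCA for reproducibility.  Voxels
unreachable through the domain (possible with pathological masks) fall back
to straight-line distance with a warning rather than erroring.

A stenosis marker splits a vessel's seeds at the given arc length;
`partition_distal()` relabels only that vessel's voxels by the same
geodesic rule against the proximal and distal seed subsets.  Markers at the
exact ends of the vessel are rejected as degenerate.

On grids up to ~32^3 the test suite checks the assignment against an
independent per-voxel Dijkstra built with igraph; agreement is exact except
at genuine geodesic ties, where either label is metrically correct and the
fixed tie order decides.

## Flow capacity

The flow-capacity map classifies each point of the joint (CFR, stress
perfusion) plane into six severity classes from scar to normal.  The class
regions form a lower-left-dominant staircase: each axis value attains the
best class whose lower bound it meets, and the final class is the more
severe of the two -- the worst axis governs.  This resolves the "and/or"
of the usual map definition, is monotone (improving either quantity never
worsens the class) and covers the whole non-negative quadrant.  The numeric
cutoffs are deliberately **not** hard-coded: they are a clinical choice
from the flow-capacity literature, shipped only as a clearly-labelled
example configuration (`inst/extdata/capacity_example.yaml`).

## Dosimetry

Dose bookkeeping follows standard CT dosimetry: per-volume CTDIvol
(32-cm phantom) scales linearly with tube current from one measured
reference value (4.6 mGy at 100 kVp / 200 mA by default); protocol totals
are sums over acquired volumes; SSDE applies the AAPM TG-204
32-cm-phantom exponential size conversion
\(f(D) = 3.704369\,e^{-0.03671937 D}\) (valid 6--55 cm; \(f(23) = 1.592\));
DLP is CTDIvol times scan length and effective dose is DLP times the chest
coefficient 0.014 mSv/(mGy.cm), which its own arithmetic identifies as a
DLP coefficient.  kVp scaling is deliberately unsupported -- attempting it
errors rather than silently extrapolating -- and the bolus-tracking
monitoring dose is excluded from totals (an optional add-on field exists).
No rounding happens inside the computation; round at presentation.

## Agreement statistics

`agreement()` implements the evaluation battery used for method comparison:
OLS of test on reference with normal-theory CIs, Pearson r (Fisher-z CI),
Lin's concordance correlation coefficient with population (1/n) moments per
its original definition (sample moments available), RMSE about the identity
line (accuracy), RMSD about the fitted line (precision), and Bland-Altman
bias with 1.96 SD limits of agreement.  These are applied in-repo to
phantom recovery experiments; reproducing animal-study agreement tables
would require the original scans and is out of scope.

## Numerical and testing choices

* Problem sizes: unit tests run phantoms at 16--32 voxels per axis; the
  end-to-end recovery and territory-fidelity checks run the full 96^3
  default grid, 49 frames, in well under a minute each.  The noise
  experiment uses 20 seeds at the two selected volume times, reusing the
  cached noiseless geometry.
* Determinism: all randomness flows through a seed in the phantom spec
  (`withr::with_seed`), and identical spec + seed reproduces bit-identical
  volumes.  Geometry is cached per (spec, condition).
* Degenerate inputs error loudly: no trigger crossing, peak at or before
  trigger, non-positive \(\Delta t\), zero net enhancement, empty masks,
  non-binary mask files, kVp mismatches, stenosis markers at vessel ends.
* Negative per-voxel perfusion values (noise) are retained in maps and in
  regional means; clamping at zero is a display option only.
* NIfTI is the canonical volume format (float32 for HU and maps, uint8 for
  masks and labels); DICOM ingestion is a non-goal.

## Known limitations

The estimator inherits the assumptions of the two-volume first-pass model:
measurements must finish before contrast outflow, V2 should sit near the
aortic peak (the suite verifies a bounded ~±2-cycle sensitivity, but larger
mistiming biases perfusion), and the two-point input average carries the
curvature bias discussed above.  The phantom's geometric simplicity means
territory Dice scores near 1 say nothing about centerline extraction
quality on real CTA.  Agreement CIs are normal-theory approximations, not
bootstrap.
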