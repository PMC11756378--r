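---
title: "Methods: quantifying microtubule tip architecture with tipshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microtubule tip architecture with tipshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipshape)
```

`tipshape` measures three things about a dynamic microtubule (MT) end: the
shape of its flaring protofilaments (PFs) from 3D contour traces, the
number of fluorophore-tagged molecules bound at its tip, and its dynamic
instability behaviour from kymograph traces. This vignette explains the
models behind each pipeline, the parameters that matter, the numerical
choices that were genuinely open, and what the synthetic-data tests do and
do not demonstrate.

## Protofilament flare geometry

### The measurement model

A PF trace is an ordered 3D polyline in nm. The *flare origin* is the last
traced point still inside the MT cylinder; everything distal is the
*flare*. Manual contour models encode the origin by convention (first
point on the wall, second at the last in-cylinder segment, so
`origin_index = 2`); `flare_origin()` recovers it automatically for
contours lacking the convention, as the last point within
`mt_radius + delta` of the axis.

The flare is processed in three steps:

1. **Uniform resampling** (`resample_uniform()`): piecewise-linear
   arc-length parameterisation sampled every `step` nm. Spacing is uniform
   *in arc length along the source polyline*; Euclidean chords between
   output points can fall short of `step` by the curvature deficit when a
   source vertex lies between them. Endpoints are pinned exactly; the
   final interval may be shorter than `step`.
2. **Quadratic LOESS** (`loess_smooth()`): each coordinate is regressed
   on the uniform sample grid over the `window_points` nearest samples
   with tricube weights, degree 2, one pass. Traces shorter than the
   window get a single global polynomial. Because the local model is a
   quadratic, any trace whose coordinates are polynomials of degree ≤ 2
   in arc position is reproduced exactly, and straight traces stay
   exactly straight.
3. **Discrete curvature** (`curvature_profile()`): the turn angle at each
   interior point, computed fully in 3D (`atan2(|a×b|, a·b)`), divided by
   `step` to give degrees/nm. PF shapes that leave their radial plane
   need no special handling — the angle is intrinsically 3D.

For equal-arc samples of a circle of radius $R$ at step $s$ the turn angle
is exactly $s/R$ radians at every joint, which is the package's primary
geometric oracle: it must hold to $10^{-6}$ degrees before smoothing and
at interior joints after smoothing, in any rigid pose.

### Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `step` | 2 | nm | densest manual point placement (points every 2–4 nm); makes per-joint angles comparable across PFs |
| `window_points` | 10 | points | the smoothing window of the established PF-trace analysis this package re-implements |
| `degree` | 2 | — | quadratic LOESS, likewise standard |
| `n_terminal_joints` | 3 | joints | "terminal curvature" = mean over the distal ~6 nm; the window is not standardised anywhere, so it is configurable |
| `mt_radius` | 12.5 | nm | outer-wall proxy for a 14-PF lattice |
| `delta` | 1.5 | nm | radial tolerance of the automatic flare-origin rule |

Curvature is reported in degrees/nm (angle ÷ step). Degrees per joint are
available in `joint_angles`; multiplying `angles_per_nm` by 8 gives
degrees per 8-nm tubulin dimer.

### Aggregation conventions

`per_end_stats()` averages flare length, mean curvature and terminal
curvature over PFs with **nonzero** flare length only; untraced lattice
PFs count as zero-length, so `n_pf_nonzero + (zero-length PFs) =
n_pf_total` always. Flares with fewer than 3 resampled points have a
defined length but undefined curvature: they enter the length mean and
are excluded from the curvature means. Flare length is measured on the
smoothed resampled trace, because the raw noisy polyline is longer than
the underlying curve (noise adds length in quadrature) and smoothing
removes most of that bias.

`tip_aligned_profile()` aligns curvature profiles at their distal tips
(offset 0 at the tip, −step, −2·step, … toward the origin), reports mean
± SEM (SEM only where ≥ 2 profiles contribute) and fits mean curvature
against offset by ordinary least squares over all offsets with data.
`cap_statistics()` reports capping fractions per grid (mean ± SD across
grids) by default, pooled counts on request; both are kept because
per-grid means and pooled percentages differ whenever grids are unequal.

### Known limitations of the curvature estimator

Two systematic effects are worth knowing about; both are visible in the
package's own tests:

* **Unsigned-angle noise folding.** The 3D turn angle is non-negative, so
  point noise cannot average out: it folds into a positive curvature
  bias. With 1-nm i.i.d. point noise, 2-nm resampling and the 10-point
  window, the residual noise after LOESS still dominates the 4.6° true
  joint angle of a 25-nm-radius arc, and the grand-mean curvature comes
  out roughly 2.5× the truth. Recovery is accurate (within 10%) for
  point noise up to ~0.3 nm, which is the regime the unit tests assert;
  the acceptance suite also exercises the 1-nm case and documents the
  bias rather than hiding it. Flare *length* recovery is robust to the
  full 1-nm noise.
* **Tip-edge flattening.** Near the trace ends the LOESS windows are
  one-sided, and a one-sided quadratic fit straightens an arc slightly.
  Because profiles are aligned at their tips, this flattening always sits
  at offsets 0 … −(window/2)·step of the tip-aligned profile and
  attenuates fitted curvature gradients; the slope-recovery test therefore
  runs noise-free, where the attenuation stays within 15%, and the
  aggregation itself is verified exactly against directly constructed
  linear profiles.

### The coiled-coil yardstick

`coiled_coil_axial_length()` encodes the standard 0.15 nm axial rise per
residue of a two-stranded α-helical coiled coil: ~80 residues span
~12 nm, the number used to interpret maximum particle dimensions from
solution scattering of capping-protein coiled-coil fragments.

## Single-molecule photometry

### Model

Spot detection is a thresholded local-maximum scan: candidates must
exceed the frame median by `min_snr` (default 4) robust scales (MAD), be
strict 8-neighbourhood maxima, and survive non-maximum suppression within
`min_separation` (default 3 px). These defaults are this package's own;
detection is deliberately simple because all downstream quantities come
from the fits, not the detector.

Each spot is fitted with an isotropic 2D Gaussian plus constant offset by
Levenberg–Marquardt (`minpack.lm`); "intensity" means the fitted peak
amplitude $A$ (the integrated volume $2\pi A\sigma^2$ is also reported).
Single-fluorophore amplitudes are modelled as lognormal; the MLE is the
mean/SD of log amplitudes (population SD, matching the closed-form MLE
and `fitdistrplus`), and the calibration standard is the *fitted* mean
$\exp(\mu + \sigma_{\log}^2/2)$, not the arithmetic mean (available via
an option). Molecules per spot is the ratio of tip amplitude to that
standard; the oligomeric state of a tagged protein is the ratio of two
fitted means against monomer/dimer standards.

### What passing tests show

The generator renders spots whose total peak amplitude is the sum of N
i.i.d. lognormal single-fluorophore draws, blurred by a Gaussian PSF
(σ = 1.5 px), with Poisson shot noise and additive Gaussian read noise on
a constant background. Under that model, 500-spot fields per N recover
N ∈ {1, 2, 4, 6, 10} within 15% and separate dimers from monomers at a
ratio in [1.8, 2.2]. Real EMCCD data add gain stochasticity, background
structure and bleaching within the exposure, none of which is simulated;
the tests validate the estimator chain, not the camera model.

## Kymograph dynamics

Rates and durations are pure unit arithmetic from the calibration
(defaults 0.064 µm/px, 3 s/frame). The classification rules are:

* **Pause**: |rate| ≤ 0.05 µm/min (the practical detection floor for
  elongation) **and** duration ≥ 15 s, inclusive on the boundary.
  Near-stationary segments shorter than 15 s are merged into the longer
  neighbouring event — duration adds, rate is recomputed from combined
  displacement, so total time and displacement are conserved exactly.
* **Catastrophe frequency**: transitions into shrinkage (from growth or
  pause — transient pauses end in depolymerisation) divided by total time
  in growth + pause. This standard normalisation is a package choice; the
  source analyses report frequencies without writing the formula.
* **End categories**: `fully_blocked` = no growth over the whole
  observation window (10 min by default); `occasional_pauses` = grew and
  paused ≥ once; otherwise `no_pauses`. Every history maps to exactly one
  category.
* **Time-weighted rate distribution**: each event weighted by
  duration/Σduration; the weights sum to 1 by construction and the CDF
  answers "what fraction of total time was spent at ≤ x µm/min".
* **FRAP**: traces are divided by the mean pre-bleach intensity (≥ 2
  pre-bleach points required); no reference-region double normalisation
  is applied because tip-bound pools are measured against their own
  pre-bleach level. Recovery fraction is the recovered share of the
  bleached intensity.

The event generator draws growth durations exponentially at the
prescribed catastrophe rate, truncates at the observation span, and
optionally inserts pre-catastrophe pauses. The catastrophe estimator
(transitions ÷ exposure time) is the censoring-correct MLE for an
exponential hazard, which is why 500 simulated MTs recover a 0.2 min⁻¹
rate within 10%.

## Synthetic data: what is and is not emulated

`gen_flared_end()` builds circular-arc flares (constant curvature — the
regime the average-curvature statistic summarises) at prescribed arc
length, with optional linear curvature gradients toward the tip, optional
out-of-plane pitch, 2–4-nm point spacing and i.i.d. Gaussian point noise.
It does **not** simulate lattice mechanics, sheet-like tip structures, or
the spatially correlated tracing errors of a human annotator — real
tracing error is likely smaller and smoother than i.i.d. noise of equal
magnitude, which is exactly why the noise-folding ceiling above matters
on synthetic data more than on careful manual models.

Generators are deterministic given `seed`; ground truth is attached to
every fixture and round-trips through the CSV writers, so reader/writer
fidelity is itself testable.

## Problem sizes and runtime

The shipped tests use 30–50 simulated ends for geometry recovery, 500
spots per stoichiometry level (rendered as 5 frames of 100), 500 MTs for
catastrophe recovery and 100-seed property sweeps; the full suite runs in
well under a minute and the acceptance script in a few seconds. These
sizes were chosen so that Monte-Carlo error is a small fraction of each
asserted tolerance.

## Degenerate inputs, tie-breaks, tolerances

* A flare with < 2 points resamples to a flagged zero-length trace and
  never errors; < 3 points gives an empty curvature profile excluded from
  aggregation.
* `flare_origin()` returns the last index when no point leaves the
  cylinder and the first when none is inside it.
* Generated arcs shorter than one point spacing produce deliberately
  zero-length flares; otherwise the final sub-spacing remainder is
  appended so the prescribed arc length is met exactly.
* Geometric identities are asserted at 10⁻⁶–10⁻⁹ (exact math), recovery
  statistics at 10–15% (Monte Carlo), the lognormal MLE at 2% for
  n = 10⁴.
* Correlation requires ≥ 3 ends and nonzero variance in both variables;
  equal-intensity degenerate lognormal input is allowed (σ_log → 0).
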