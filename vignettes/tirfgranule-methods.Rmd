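---
title: "Methods: granule docking, fusion and enrichment quantification"
author: "tirfgranule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granule docking, fusion and enrichment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfgranule)
```

This vignette records the models, parameter choices and numerical
decisions behind `tirfgranule`, in the spirit of a methods section: what
each stage assumes, which knobs matter, and what validation on synthetic
data does and does not establish about real recordings.

## The imaging model behind the simulator

TIRF illumination restricts excitation to the first one or two hundred
nanometres above the coverslip, so membrane-proximal secretory granules
appear as diffraction-limited spots on a fluorescent background. The
simulator renders each granule as an isotropic 2-D Gaussian (sd
`psf_sigma`, default 1.3 px at 100 nm/px — a realistic PSF width for a
high-NA objective at green/red wavelengths), adds a constant expected
background (`background_level`, photons), draws per-pixel Poisson shot
noise, adds Gaussian read noise (`read_noise_sd`), clips at zero and
quantises to 16 bits with a saturation clamp — the minimal model matching
EMCCD statistics qualitatively. The convenience argument `snr` sets the
spot amplitude to `snr` background-noise standard deviations, so "SNR 10"
movies have a peak 10 noise-sd above background.

Granule kinetics follow a three-kind mixture (`residence_model`): an
arriving granule is long-lived ("docked", probability `p_dock`), a
transient visitor, or (optionally) a laterally mobile transit. Confined
granules jitter around an anchor with per-frame Gaussian displacements of
sd `confinement_sd` (default 0.3 px, i.e. 30 nm — tight enough that the
confinement classifier is discriminative); transits drift ballistically
at `transit_speed` (default 2 px/frame). Axial approach is rendered as a
2-frame intensity ramp (half, then full amplitude), matching the visual
impression of a granule entering the evanescent field. Residence-time
samplers default to uniform 45–120 s for docked granules (comfortably
beyond the 40 s survival horizon) and uniform 2–20 s for visitors (at or
above the 2 s approach minimum, below the 25 s docking threshold).

What the generator deliberately does **not** model: evanescent-field
depth decay (axial position is binary — in or out), EMCCD gain-register
noise, photobleaching, stage drift, and granule–granule interactions.
Passing parameter-recovery tests on these movies therefore demonstrates
the correctness of the measurement chain under the stated noise model; it
does not certify performance on recordings with strong bleaching or
drift, which would need correction upstream.

## Spot detection

The detector mirrors the noise-tolerance semantics of the ImageJ
"find maxima" routine: after Gaussian smoothing (`smoothing_sigma`,
default 1 px), a local maximum is reported iff its *prominence* — its
height above the highest saddle connecting it to a higher maximum — is at
least `prominence`. This is computed exactly by topological persistence:
pixels are processed in decreasing intensity order while components grow
in a union–find structure; when two components meet, the lower peak dies
and its persistence is its height above the merge level. Ties break by
pixel index, so detection is deterministic. Because the global maximum of
*any* image survives with persistence equal to the full range, peaks must
additionally rise `prominence` above the smoothed median (the background
level); without this floor a spot-free noise frame would always yield one
spurious detection.

The default `prominence = NULL` adapts per frame to 5× the robust
background sd (MAD of the smoothed frame). Positions are refined by a
3 × 3 centre of mass, which reaches roughly 0.1–0.2 px accuracy at
SNR 10 — necessary, since the confinement classifier works at a 0.3 px
jitter scale. `min_separation` (default 3 px) drops the less prominent of
any closer pair. Density is count over footprint area, the footprint from
a user-supplied mask or an Otsu threshold of the temporal mean
(`footprint_mask`), with area in µm² from the pixel size.

Two close granules interact through the saddle rule: below ~4 px
separation the weaker peak's prominence collapses and it is intermittently
suppressed. This is inherent to the prominence semantics, and is the main
loss mechanism at high densities; the tracking layer compensates (below).

## Tracking and docking classification

Linking is greedy nearest-neighbour, closest pair first, gated at
`link_radius` (3 px) with up to `max_gap` (1) missed frames. Granule
densities at the membrane are low enough that globally optimal assignment
would add complexity without changing results. A track's residence is
`(end − start + 1) × frame_interval`; confinement holds iff its maximum
excursion from the median position stays within `confine_radius`.

The dwell-time rules are the field's standard: an appearance that stays
confined ≥ 2 s (`t_min`) is an approach; ≥ 25 s confined (`t_dock`) is
docked, with ties at exactly 25 s classified docked; shorter approaches
are visitors; unconfined or sub-2 s contacts are transits. Stable docking
is scored as presence 40 s (`t_survival`) after the approach frame.
`confine_radius` defaults to 1.5 px (150 nm); the criterion "laterally
confined" has no published radius, so the value is an explicit parameter
echoed into every manifest.

`docking_fraction` counts approaches among tracks that appear *after* the
first frame (granules already present belong to the standing pool, which
enters density but not arrival counts). Before counting, continuation
fragments are chained: a track that begins within 2 px of where another
ended at most 10 frames earlier is a re-detection after a transient
dropout (typically saddle suppression by a passing neighbour), not a new
axial approach — the judgement a manual scorer would make. Chains must be
confined in every fragment; their span determines approach status and
40 s survival. Without this rejoining step, each dropout would both
inflate the approach denominator and erase a stably docked granule,
biasing the fraction downward by several percentage points at realistic
densities.

## Fusion-event detection

Exocytosis shows as a loss of the granule marker completed within one or
two frames. The detector works on background-corrected track intensities
(per-frame median background when the movie is supplied) and extends each
track past its last detection by sampling the 3 × 3 mean at the final
position, so the post-loss level is measured even though the spot is no
longer detectable. An event is called at the first index whose intensity
falls below `drop_fraction` (0.5) of a reference level taken from five
frames ending two frames before the candidate, provided that:

* at least one of the three immediately preceding frames still reaches
  0.8 of the reference (an abrupt step, not a decay — a mean here would
  let isolated Poisson dips mimic gradual loss, a maximum tolerates
  them);
* no frame in the following five recovers above 0.75 of the reference
  (no reappearance within 5 frames);
* the post-event five-frame mean stays below half the reference; and
* the track has at least `min_pre_frames` (3) detections before the
  drop, so an isolated spurious detection can never be scored.

The event frame is walked back to the first frame departing from full
intensity, and events too close to the movie end for a post window are
discarded. A 10-frame linear decay to background is rejected by the
step-sharpness test deterministically; a clean half-loss within two
frames is accepted. Thresholds are parameters and are reported in the
event table (`pre_mean`, `post_mean`, `drop_frames`).

Exponential fits use a log-linear regression (offset pinned just below
the minimum) for starting values, refined by Levenberg–Marquardt
(`minpack.lm::nlsLM`). Constant traces are refused as unidentifiable;
non-decreasing traces are refused; non-convergence of the refinement is
flagged (`converged = FALSE`) with the log-linear estimate returned.

## The enrichment statistic

For each cell, crops of 30 × 30 px are centred on at least 15
marker-positive structures (fewer triggers a warning) and averaged into a
projection per channel. Profiles are sampled along the main diagonal by
bilinear interpolation at `round(side × √2)` points (42 for 30 px), i.e.
approximately 1 px spacing. The granule width `N_gr` is the FWHM of the
*marker* profile above its minimum, with crossings located by linear
interpolation; the enclosed interval is the granule region applied to the
*probe* profile. With `min` the probe-profile minimum,

$$E = \frac{AUC_{gr} - N_{gr}\cdot min}{AUC_{All} - N_{All}\cdot min},
\qquad E_{null} = \frac{N_{gr}}{N_{All}}.$$

`E` lies in [0, 1] (every sample is ≥ `min`, and the granule region is a
subset of the profile) and is invariant under affine rescaling of the
probe (`min` transforms identically). For a probe independent of the
granule the statistic approaches the null; for a *linear* background the
identity is exact when the granule region is centred, and a smoothly
curved background perturbs it by only a few percent — the deviation is
scale-invariant, so "weak" and "strong" gradients of the same shape give
the same `E`. At exact uniformity the expression is 0/0; a guard
(denominator ≤ 10⁻⁶ × N_All × max|profile|) flags the result rather than
returning a number.

Two integration rules are provided. The default trapezoid rule integrates
the interpolated profile, replacing the sample counts by the matching
integration lengths (`hi − lo` and `N_All − 1`) so the algebra — bounds,
null, invariance — holds exactly. The rectangle rule (plain sample sums
over integer indices) exists because it is hand-checkable; the worked
example in the test suite evaluates it on an 8-sample profile to
`E = 11/13`. Because the preferred summary of a bar plot is ambiguous
(`E`, the excess `E − E_null`, or peak-over-baseline), the result object
reports all three and leaves the choice to the caller.

## Footprint traces

Traces are background-corrected (scalar or per-sample background; in
practice a cell-free region's mean) and divided by the mean corrected
fluorescence over the pre-stimulus baseline window, so the F/F₀ baseline
is exactly 1 and normalisation is idempotent and scale-invariant. The
maximal response is the maximum of F/F₀ − 1 inside the stimulus window
after a 3-point running median — a guard so a single-frame event cannot
dominate a per-cell statistic. Reuptake is the single-exponential τ of
the post-stimulus segment, with fractional recovery reported at a stated
horizon (default 60 s). The trace simulator uses a saturating rise
(`rise_tau`, default 2 s) to a plateau and an exponential return; its
footprint-averaged noise default in the tests (sd 0.5 AU on a baseline
of 100) reflects that footprint traces average thousands of pixels and
are far less noisy than single-spot intensities.

## Statistics layer

Condition summaries are mean ± SEM over cells, the convention of the
source experiments. Comparisons are two-tailed paired or unpaired
Student's t tests (`stats::t.test`; Welch is deliberately not used for
the unpaired case to match the classical test), with percent change
`(mean_a − mean_b)/mean_a × 100` and its SEM propagated in quadrature.
Degenerate inputs (zero-variance differences, as arise with synthetic
data and perfect detection) return p = 1 for equal means and p = 0
otherwise instead of erroring. Two-way ANOVA with Tukey's post hoc test
delegates entirely to `aov` + `TukeyHSD` and is validated against a
hand-computed balanced 2 × 2 example — no bespoke implementation is
claimed. OLS trends come from `lm`, reporting slope, R² and the slope
t-test p.

## Problem sizes and seeds

Validation uses movie sizes chosen to embody the study conditions at
realistic membrane densities: docking parameter-recovery runs use
200 granule approaches spread over 700 one-second frames on a
300 × 300 px (900 µm²) field at SNR 10 — about 13 concurrent granules,
comparable to a sparse cell footprint, keeping close encounters (the
saddle-suppression regime) rare. Fusion recovery uses 30 and 9 events on
200 × 200 px, 60 frames at SNR 5; density and structure-count recovery
use single 250 × 250 px (625 µm²) fields with 6 px minimum spacing. All
generators take explicit seeds; the acceptance script derives one
sub-seed per stage from a single master seed, and a fixed seed reproduces
every artifact bit for bit.

## Known limitations

* Axial (z) information is not estimated from intensity; "approach" is
  detection onset.
* The fusion detector implements the loss criterion only; transient
  brightening ("flash") before loss is not required or used.
* Sub-0.1 px localisation (Gaussian fitting) is out of scope; the 3 × 3
  centre of mass is adequate for classification, not for nanometre
  displacement analysis.
* Kiss-and-run versus full fusion is not discriminated.
* At granule separations below ~4 px the prominence rule suppresses the
  weaker spot; the continuation-chaining in `docking_fraction`
  compensates for the resulting dropouts, but two granules docked
  permanently within that range are counted as one.
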