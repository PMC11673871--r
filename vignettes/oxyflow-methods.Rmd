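---
title: "Breath-hold NIRS oxygenation-flow analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold NIRS oxygenation-flow analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyflow)
```

## The physiological signal and the measurement model

A short end-exhalation breath-hold engages oxygen-conserving reflexes:
peripheral vasoconstriction during the hold, then a hyperemic recovery once
breathing resumes. In peripheral tissue this appears as a rise in
deoxyhemoglobin (HbR) during the hold and, during recovery, an overshoot of
oxyhemoglobin (HbO) and oxygen saturation (StO₂) with an HbR undershoot,
settling toward a new baseline roughly 40 s into recovery. The default
acquisition paradigm is 40 s rest, 20 s hold, 60 s recovery at 1 Hz per
wavelength (`paradigm()`); every stage takes the paradigm object explicitly,
so none of the frame numbers below are hard-coded.

The scanner measures diffuse reflectance at 682 and 826 nm — one wavelength
on each side of the ~797 nm isosbestic point, so the pair separates HbO from
HbR. A white calibration sheet imaged before the study provides the
per-pixel reference intensity. Attenuation relative to that reference,

$$\Delta OD(\lambda, x, y, t) = \log_{10}\frac{I_{cal}(\lambda, x, y)}{I(\lambda, x, y, t)},$$

is modelled by the modified Beer–Lambert law as linear in the effective
chromophore concentrations, $\Delta OD = E\,(HbO, HbR)^T$, with $E$ the 2×2
extinction matrix. We solve this system per pixel and frame with the
differential pathlength and geometry factor set to 1. That scale choice is
deliberate: the pipeline only ever uses percent changes and correlations,
both invariant to a global multiplicative factor, so "effective"
concentrations in arbitrary units lose nothing. For the same reason the
default extinction coefficients (approximate values from the standard
compiled hemoglobin spectra; `extinction_matrix()`) are configuration, not
science — any well-conditioned pair gives identical correlation maps and
OFIs.

Two conventions deserve a note:

* **Reference choice.** ΔOD is computed against the calibration sheet, not
  against the first tissue frame. Recovered HbO/HbR then behave as
  positive absolute-like effective concentrations, which makes the
  saturation ratio StO₂ = HbO/(HbO+HbR) well defined at every frame; the
  temporal "Δ" is taken later, at the profile stage, relative to breath-hold
  onset.
* **StO₂ definition.** The ratio definition is the default. Where a
  difference-type oxygenation index is preferred, `sto2_mode = "difference"`
  stores HbO − HbR instead; the switch is explicit, never silent. With the
  ratio definition, pixels with |HbT| below a guard (10⁻⁶ a.u.) are flagged
  invalid rather than clipped, so near-degenerate ratios cannot leak into
  downstream statistics.

## Motion correction

Frames are registered rigidly (rotation + translation, exactly the motion a
mounted foot exhibits) to the first frame, the transform estimated on the
826 nm channel — both channels share one camera and move together — and
applied to both channels and to the calibration reference, keeping
tissue/reference ratios co-located. Pixels resampled from outside the frame
are flagged invalid and excluded from every downstream statistic rather than
imputed.

The estimator is intensity-based: a coarse stage scans candidate rotations
(±5° by default), solving the translation for each by FFT
cross-correlation, and a Nelder–Mead refinement maximises normalised
cross-correlation. One numerical point matters: comparing a once-resampled
image against a pristine one biases the optimum toward integer offsets,
because bilinear interpolation blurs only at fractional shifts and the blur
penalty competes with the alignment signal. The refinement therefore
resamples *both* frames toward the transform midpoint (symmetric
resampling), equalising the blur; on band-limited frames this recovers
programmed transforms to ~0.05 px and ~0.06°, comfortably inside the 0.5 px
/ 0.5° the tests demand. Estimates below 0.01 px/degree snap to the exact
identity so motion-free stacks pass through bit-for-bit. Rotation is only as
observable as the image content allows: on images that are exactly
piecewise-constant with axis-aligned edges (an adversarial case for any
interpolating metric) rotational accuracy degrades to a few tenths of a
degree, which is why the synthetic scenes offer a static spatial texture and
fiducial markers, and why real frames — smooth diffuse reflectance with
fiducials — pose no such problem.

## Profiles, smoothing, normalisation

Each pixel's time-series is smoothed with a Savitzky–Golay filter, applied
as a T×T linear operator built from the local least-squares projections
(interior rows are the central FIR coefficients; the first and last
half-windows use the corresponding projection rows, i.e. polynomial edge
handling, not truncation). Defaults are window 11 frames, order 3 at 1 Hz:
wide enough to suppress frame-to-frame sensor noise, short enough to leave
the 20 s-scale physiological features untouched (the filter reproduces
cubics exactly). Pixels whose series contains invalid frames are left
unsmoothed; validity is never altered by filtering.

ROI profiles are per-frame means over valid ROI pixels. They are normalised
as percent change from the onset value at t = rest_s (frame 41 by default):
$100\,(S(t) - S(t_0))/|S(t_0)|$, retaining t ≥ t₀. The absolute value in
the denominator keeps signs stable should an effective concentration be
negative. A zero onset value is an error (the pixel/ROI is excluded and
reported), except that re-normalising an already-normalised profile at the
same onset is the identity. Grand averages across subjects and repetitions
are pointwise means with standard error sd/√n.

## Correlation maps and the OFI

Flow synchrony is zero-lag Pearson correlation, computed per pixel between
the pixel's StO₂ series and a reference series over the analysis window.
The window defaults to the hold plus the first hold-length of recovery
(t = 41–80 s, 40 frames), where the stimulus-locked changes concentrate;
it follows the paradigm object, so a different protocol shifts it
automatically. The reference is the whole-foot mean StO₂ for intact feet;
for wound cases it is a background ROI that the user must supply explicitly
— the package refuses to auto-select one, and records its centroid, because
"background, away from the wound" is a clinical judgement. Correlation is
computed on smoothed, *unnormalised* StO₂: the onset normalisation is an
affine map, to which Pearson correlation is invariant, so this choice is
observationally equivalent while avoiding onset-division failures at
degenerate pixels.

Zero-variance pixels return an invalid marker, never 0 — a 0 would
masquerade as "uncorrelated" and bias the index. Fiducial squares and any
user exclusions are likewise invalid. The OFI is the median (robust to the
skewed, bimodal distributions that wounds produce) of the valid PCC values,
in percent; for wound cases the wound region is excluded by default
(`exclude_wound`), matching the idea that the index summarises the
perfusion competence of the rest of the foot. The shipped 28% threshold
(strict `<`, so exactly 28% classifies "above") originates from a separate
clinical study and is a configurable default, not something this package
validates.

## The synthetic scene generator

With no subject data available, the generator is the package's ground
truth. It emulates: the 120 s / 1 Hz acquisition; a response family of
piecewise-linear ramps with exponential plateau approach — HbR rising by
`hold_hbr_rise` during the (possibly delayed) hold, HbO overshooting by
`recovery_hbo_overshoot` and HbR undershooting by
`recovery_hbr_undershoot` during recovery, settling at `plateau_time_s`
and drifting 20% of the excursion back toward baseline afterwards (the
"new baseline" behaviour); region-dependent onset delays (20–40 s for
wound-like tissue); sign-inverted responses for non-healing wound beds;
a static, wavelength-shared multiplicative melanin transmission factor per
region; optional static spatial texture; near-zero fiducial squares;
per-frame rigid motion; and multiplicative Gaussian sensor noise (an
adequate model for shot/readout noise on a bright reflectance signal).
Frames are rendered through the exact forward model the mBLL stage inverts,
so with noise and motion off the round trip is float-exact, and ground-truth
series are emitted alongside the stack so tests never re-derive them.

Default magnitudes: baselines give a resting StO₂ of 60%, and the
fractional changes (2% HbO overshoot, 2.5% HbR undershoot, 2% hold rise)
reproduce the ~2% post-hold saturation plateau typical of control feet. The
melanin factor is static and shared across wavelengths because a breath-hold
does not change melanin concentration; its attenuation enters ΔOD as a
time-constant additive offset at both wavelengths, hence a constant offset
in recovered HbO/HbR — which is exactly why temporal correlation analysis is
insensitive to skin tone, a property the tests make exact (profile
correlations > 0.99 between regions with melanin transmissions 1.0 and 0.4).

What the generator does *not* emulate — layered skin optics, wavelength-
dependent melanin spectra, scattering changes, cardiac/respiratory bands,
spatially heterogeneous physiology within a region, calibration-sheet
non-uniformity — bounds what passing tests show: they validate the
pipeline's mathematics and its contracts, not clinical performance on real
feet.

## Numerical choices and problem sizes

* 2×2 mBLL inversion by direct solve; invertibility and conditioning of E
  are checked at construction.
* Saturation guard 10⁻⁶ a.u.; invalidity propagates, it is never imputed.
* Pearson denominators of exactly zero return the invalid marker; values are
  clipped to [−1, 1] only against floating-point overshoot.
* Median with the standard even-count convention (mean of the two central
  order statistics).
* Registration: coarse rotation grid 1°, Nelder–Mead reltol 10⁻¹⁰ with one
  restart, sub-0.01 identity snapping.
* Test and acceptance problem sizes are chosen to exercise every contract
  while staying desk-scale: full 120-frame stacks at 256×256 for the
  round-trip check, 128×128 for single-run OFIs, 96×96 for the 100-replicate
  ordering study, 64×64 elsewhere; short paradigms (10/5/15 s) where only
  mechanics, not the response shape, are under test.

## Known limitations

* Effective concentrations are relative; no absolute quantification (µM) and
  no scattering separation.
* Rigid registration only — no toe tracking or deformable correction.
* Rotation estimation requires rotationally informative content (realistic
  for fiducial-marked feet; degenerate for synthetic piecewise-constant
  scenes without texture).
* The OFI threshold is imported, not validated here; classification output
  is a convenience, not clinical decision support.
* Lagged or frequency-domain synchrony is out of scope; the statistic is
  zero-lag Pearson correlation only.
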