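# oxyflow

Breath-hold near-infrared spectroscopic (NIRS) imaging of peripheral
oxygenation flow, for researchers assessing tissue perfusion in the foot —
in particular the healing potential of diabetic foot ulcers (DFUs).

A short end-exhalation breath-hold triggers peripheral vasoconstriction
followed by a hyperemic recovery. Imaging the foot with a dual-wavelength
(682/826 nm) diffuse-reflectance scanner at 1 Hz through a timed paradigm —
40 s rest, 20 s breath-hold, 60 s recovery — captures this response as a
spatio-temporal oxygenation signal at every pixel. In healthy tissue the
response is synchronous across the whole foot; compromised wound beds
respond late, weakly, or with inverted sign. `oxyflow` turns raw image
stacks into maps and indices of that (a)synchrony.

## Method

1. **Rigid motion correction.** Every frame is registered to the first frame
   by intensity-based rotation + translation estimation (FFT
   cross-correlation seeding, symmetric-resampling NCC refinement); the same
   transforms are applied to the calibration reference so tissue/reference
   ratios stay co-located.
2. **Modified Beer–Lambert law (mBLL).** With a white calibration sheet as
   the reference intensity, the attenuation at wavelength λ is
   ΔOD(λ, x, y, t) = log₁₀[I_cal(λ, x, y) / I(λ, x, y, t)], and the
   2×2 extinction system ΔOD = **E** · (HbO, HbR)ᵀ is solved per pixel and
   frame (unit effective pathlength), giving effective ΔHbO, ΔHbR,
   ΔHbT = ΔHbO + ΔHbR and saturation StO₂ = HbO / HbT.
3. **Concentration profiles.** A Savitzky–Golay filter (window 11 frames,
   order 3) smooths each pixel's time-series; ROI averages are normalised as
   percent change from breath-hold onset (t = 40 s).
4. **Flow-correlation map.** For each foot pixel, Pearson's correlation
   coefficient between that pixel's StO₂ series Y and a reference series X
   over the 40 s analysis window (t = 41–80 s: hold + early recovery):

   PCC = Σᵢ(Xᵢ − X̄)(Yᵢ − Ȳ) / √[Σᵢ(Xᵢ − X̄)² · Σᵢ(Yᵢ − Ȳ)²]

   The reference is the whole-foot mean StO₂ for intact feet, or a
   user-chosen background ROI away from the wound for wound cases.
5. **Oxygenation Flow Index (OFI).** The median of the map's PCC
   distribution, in percent. Low OFI marks asynchronous flow; a configurable
   threshold (default 28%, strict `<`) flags feet whose wounds tend not to
   heal.

Because no subject imaging data are publicly available, the package ships a
first-class synthetic scene generator that renders programmable breath-hold
responses — delays, inverted wound beds, per-region melanin attenuation,
fiducial markers, rigid motion, sensor noise — through the forward optical
model, so every stage is testable against known ground truth.

## Worked example

Simulate a non-healing DFU-like foot (30% of the foot inverted in its
response), analyse it with a background-ROI reference, and summarise:

```r
library(oxyflow)

scene <- dfu_scene(size = 96, noise_sd = 0.01, wound = "inverted")
rd <- render_stack(scene, seed = 7)

cfg <- bh_config(register = FALSE, reference_mode = "roi",
                 reference_roi = rd$masks$B1)
res <- bh_analyze(rd$stack, rd$calibration, rd$masks$foot,
                  wound_mask = rd$masks$W,
                  rois = list(B1 = rd$masks$B1, B2 = rd$masks$B2, W = rd$masks$W),
                  exclusions = list(rd$masks$fiducial), config = cfg)
summary(res)
#> OFI 96.3% (above at threshold), 4012 pixels; reference roi:B1, window 41-80 s
#> PCC quartiles: 94.9 / 96.3 / 97.3 %
#> Pairwise ROI correlations:
#>   roi_a roi_b        pcc
#> 1    B1    B2  0.9998895
#> 2    B1     W -0.9999465
#> 3    B2     W -0.9998840
```

Reading the output: the two background regions are near-perfectly
synchronous (PCC ≈ 1) while the wound is anti-correlated (PCC ≈ −1) with
both, exactly as programmed. The OFI of 96.3% is the median over the foot
*excluding* the wound region (the default for wound cases); including it
(`compute_ofi(res$corrmap, exclude_wound = FALSE)`) drops the index, and
`plot(res)` shows the wound as a blue (asynchronous) patch in an otherwise
red (synchronous) map. `write_analysis(res, "out/")` persists maps,
profiles, transforms, the OFI table and the resolved configuration.

A command-line wrapper for simulation and analysis lives at
`inst/cli/oxyflow.R` (`Rscript oxyflow.R simulate|run ...`).

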