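---
title: "Processing model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpsimri)
```

## The problem

Hyperpolarized ²⁹Si MRI detects antibody-functionalized silicon particles
that bind to mucin-1-positive colorectal lesions. The silicon signal is
transient and sparse, acquired at low resolution (nominally a 32 × 32
matrix over a 64 mm field of view), and sits on a background of receiver
noise plus several characteristic artifacts: particles left in the
injection syringe, particles spilled outside the body, day-to-day receiver
drift, and RF overflow (ADC clipping) when the hyperpolarized signal
exceeds the converter's dynamic range. A ¹H anatomical volume (256 × 256,
22 slices, 0.75 mm thick) is acquired immediately afterwards without
moving the subject. Raw, per-study auto-scaled displays of such data
cannot be compared across studies or sessions; this package implements the
post-acquisition chain that makes them comparable.

## The processing chain

Per study:

1. **Reconstruction.** The 32 × 32 silicon k-space (stored DC-at-center)
   is zero-filled symmetrically to 256 × 256 — periodic-sinc interpolation
   onto the anatomical grid, adding no information — and passed through
   the centered inverse 2D DFT with 1/(rows·cols) normalization. The
   modulus is kept; phase is discarded because every downstream statistic
   assumes a nonnegative image.
2. **Noise estimation.** The four corner patches of the reconstructed
   image (corner fraction 1/8 per axis, i.e. 32 × 32 patches on the 256
   grid) are pooled; their sample mean and standard deviation define the
   per-study background. For complex-Gaussian acquisition noise the
   magnitude background is Rayleigh, with mean σ√(π/2); the corner mean is
   therefore a per-study noise level that adapts to day-to-day variation.
3. **Masking.** An optional user-drawn quadrangle restricts analysis to
   the subject's body, excluding the syringe track and spills. Membership
   is an even–odd crossing test on pixel centers, boundary inclusive.
4. **Threshold denoising.** Pixels below 5 × the mean corner background
   are zeroed (strict comparison: a pixel exactly at the threshold
   survives). The multiplier is a parameter; 5 is the default.
5. **Phantom normalization.** All intensities are divided by the scalar
   silicon-oil phantom signal recorded before injection, cancelling
   receiver drift: scaling the acquisition and the phantom by a common
   factor provably leaves the result unchanged.

Across studies: all phantom-normalized images in one manifest are divided
by the single **universal peak**, so the set shares one intensity scale
with global maximum exactly 1 and all between-study ratios preserved.
The manifest is the comparison unit — the natural scope for a cohort or
longitudinal comparison.

For display, the chosen anatomical slice is contrast-stretched with 1%
tail saturation (rank rule k = ⌈p·n⌉ per tail, clamp then linear rescale)
and the silicon map is fused over it with intensity-proportional alpha
(α = 0.7 · silicon, "hot" colormap), so zero-silicon pixels show pure
anatomy. Registration is the identity by design: both nuclei are imaged
without moving the subject, so grid matching via zero-fill is the only
spatial operation.

## Quantification

With μ_t the mean over the tumor ROIs (standard 7 mm diameter circles),
μ_b, σ_b over equal-diameter circles shifted to non-tumor regions, and
μ_m, σ_m over the torso polygon minus the tumor ROIs:

$$\mathrm{SNR} = \frac{|\mu_t - \mu_b|}{\sigma_b}, \qquad
  \mathrm{CNR} = \frac{|\mu_t - \mu_m|}{\sigma_m}.$$

Both ratios are invariant under positive affine rescaling, so the choice
of normalization stage cannot affect them. Cohorts are compared with
one-way ANOVA computed from between/within sums of squares (auditable
against hand calculation), with the p-value from the F survival function.

**Which image is quantified.** ROI statistics use the masked,
phantom- and set-normalized image *without* the display threshold. This
is deliberate: the 5× threshold removes essentially every background
pixel (the Rayleigh tail above 5·σ√(π/2) has probability ≈ 3 × 10⁻⁹), so
σ_b on a thresholded image is identically zero and SNR is undefined —
and control studies, which carry no supra-threshold signal inside the
body, would be identically zero images. The background level is
established per study before the image is altered for display; the
threshold is a display operation. `run_process()` therefore writes both
images per study: `<id>_silicon.nii` (displayed, thresholded) and
`<id>_silicon_quant.nii` (quantified, un-thresholded).

## Numerical choices

* **Zero-fill placement.** For padding amount *e*, ⌈e/2⌉ zero rows/columns
  go before the block and ⌊e/2⌋ after, keeping the Nyquist row with the
  leading block. Any fixed rule works; fixing one makes outputs
  bit-reproducible. With this rule the fine reconstruction sampled at the
  original coarse positions equals the coarse reconstruction up to the
  single scale factor n²/N² (verified to 1e-8 in the tests).
* **Coordinates.** 0-based row/column indices, row 0 at the top; pixel
  centers at (i + 0.5, j + 0.5) pixel units; mm = pixel units × spacing.
  One convention everywhere avoids half-pixel registration bugs.
* **Boundary rules.** Threshold: strictly-below is zeroed. Polygon: points
  on an edge count inside. Circle ROI: distance ≤ radius. Contrast
  stretch: pixels ≤ lo map to 0, ≥ hi to 1; a constant image maps to 0.5.
* **Statistics.** Sample standard deviations use n − 1 throughout.
* **Phantom reference.** The per-study phantom is reduced to one positive
  scalar, its maximum magnitude — the simplest reproducible statistic for
  a quantity whose on-disk representation is not otherwise pinned down.
* **Degenerate inputs** raise errors rather than returning silently
  (all-zero phantom, zero-variance background, zero-area quadrangle,
  all-identical ANOVA groups, empty manifests).

## The synthetic study generator

No animal data are distributed, so `synth_params()` /
`make_study_set()` generate complete studies that exercise every pipeline
stage:

* **Geometry.** A torso ellipse (semi-axes 14 × 24 mm) with two Gaussian
  tumor foci inside it (radii 4 and 3.5 mm — lesions in the model system
  are 5–10 mm across — amplitudes 1 and 0.8), a syringe beacon outside the
  caudal torso edge (amplitude 3, i.e. 3× the brightest focus) and a
  spill blob lateral to the torso (amplitude 2). Blob sd is radius/2, so
  every structure is resolvable at the 2 mm silicon pixel; markedly
  sub-pixel blobs would be dominated by k-space truncation ringing, which
  would contaminate the corner noise patches. Artifact positions keep
  several sd of clearance from the corner patches, which must remain
  signal-free because they define the background.
* **Noise.** Noise is added in k-space as i.i.d. complex Gaussian
  (σ = 1.6 per channel on the 32 grid, i.e. image-domain channel
  σ = 0.05), so the magnitude background is exactly Rayleigh — the
  correct MR noise model. Unit-amplitude foci then sit at 20× the image
  noise σ, strong but plausible for an acquisition timed near peak
  polarization.
* **Cohorts.** `make_study_set()` writes 4 cohorts × n studies: targeted
  at full tumor amplitude, the three controls (biological, chemical,
  pre-blocked) at amplitude 0 — the pipeline sees intensity, not biology —
  with noise and artifacts retained. A per-study lognormal drift factor
  (sd 0.15 on the log scale) multiplies both the acquired signal and the
  phantom reference, emulating the day-to-day fluctuation that phantom
  normalization exists to cancel.
* **RF overflow** is modeled as symmetric hard clipping of the real and
  imaginary k-space channels at `clip_level`, the mechanism by which ADC
  overflow corrupts hyperpolarized acquisitions; receiver-gain autoprescan
  behavior is not modeled.

Everything is deterministic given the seed, to the byte, including the
on-disk files.

What the generator does **not** emulate: physiological texture of real
silicon distributions, motion and aliasing artifacts, T₁ decay during the
echo train, susceptibility effects, or coil sensitivity profiles. Passing
tests demonstrate that the processing chain is mathematically correct and
recovers planted structure under the stated noise model — not that the
pipeline's thresholds are optimal for any particular scanner.

## Problem sizes used by the tests

The test-suite and acceptance script run the silicon chain at the full
32 → 256 zero-fill. The brute-force DFT oracle runs on ≤ 8 × 8 matrices
(it is O(n⁴)); end-to-end cohort recovery uses 4 × 3 studies over 20
seeds in memory; on-disk pipeline tests shrink the anatomical stack to a
few slices while keeping the full in-plane grid. These sizes were chosen
so the whole suite completes in well under a minute while leaving every
code path at its production matrix size.

## Known limitations

* Identity registration only; any subject motion between the two
  acquisitions is not corrected.
* The quadrangle ROI and all circle ROIs come from the manifest; there is
  no interactive drawing.
* ANOVA is the only inferential procedure (no post-hoc pairwise tests).
* Clipped (RF-overflow) acquisitions are generated and flagged by their
  effect on reconstruction, but no declipping correction is attempted.
* The k-space dialect is a documented stand-in; genuine vendor raw
  directories are out of scope.
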