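---
title: "Counting single RNA molecules: models and methods in qdfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting single RNA molecules: models and methods in qdfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdfish)
```

## The problem

Single-molecule fluorescence in situ hybridization (smFISH) labels individual
RNA transcripts with fluorescent probes so that each molecule appears as a
diffraction-limited spot in a microscope image.  Transcript abundance per
cell is then a *counting* problem: decide, for every candidate spot, whether
it is a labeled molecule or a fluctuation of the cellular autofluorescence
background.  The difficulty of that decision depends on the probe: organic
dyes are dim relative to autofluorescence and photobleach within seconds to
minutes, while quantum dots (QDs) are an order of magnitude brighter and
photostable — which is what makes QD-based counting robust to the detection
threshold and to the long exposures needed for 3D stacks.

qdfish implements the complete quantification chain: a calibrated spot
detector, single-fluorophore intensity calibration from photobleaching
traces, labeling-density estimation, threshold-sweep and photostability
analyses, 2D/3D counting, condition comparisons — and a ground-truthed
synthetic image generator used to validate all of it.

## The detection model

**PSF.** The microscope point spread function is a symmetric 2D Gaussian
with standard deviation `sigma_px` (user-supplied, from wavelength/NA or
bead measurements; there is no universally correct default, 1.2 px is
typical for a 100x/1.45 objective at ~600 nm with 160 nm pixels).  The
kernel is *sampled at pixel centres* and normalised so the full discrete
kernel sums to one.  Sampling (rather than integrating over pixel area) is a
convention; because the simulator and the fitter share it, fitted positions
and amplitudes are unbiased with respect to simulated truth, and a fitted
amplitude equals the spot's total photons.  Coordinates are 0-based with the
pixel centre at the integer coordinate.

**The window test.** Every fully interior 7×7 window (`window_half = 3`) is
tested:

* H0: the 49 pixels are a constant background plus iid Gaussian noise;
* H1: they additionally contain one PSF-shaped spot at the window centre.

Both hypotheses are fitted by least squares, and the generalized likelihood
ratio statistic is `T = N log(SS0/SS1)` with `N = 49`.  The test is
one-sided: a negative fitted amplitude (a dark dip) scores 0.  Because the
background is refitted in every window, detection responds to *local*
background — essential under the spatially varying autofluorescence of a
cell.  `T` is invariant under affine rescaling of the pixel values, so the
calibration below transfers across illumination and gain settings.

**Threshold calibration in dB.** Detection stringency is expressed as the
probability of a false positive per image on a decibel scale:
`P_img = 10^(-threshold_db/10)`.  The per-image budget is divided over the
`(H-6)(W-6)` interior windows (Bonferroni; 506² ≈ 2.6·10⁵ windows for a
512×512 frame), giving a per-window probability `p`, which is mapped to a
cutoff on `T` either asymptotically (`qchisq(1-p, df = 1)`, one extra linear
parameter under H1) or by Monte Carlo.  The asymptotic mapping ignores the
one-sided convention and the finite-sample 49-pixel tail, so it is
conservative at small `p`; the Monte-Carlo mode is exact.

**Monte-Carlo calibration without simulating pixels.**  Under H0 the
statistic depends on the noise only through its orthogonal decomposition:
with `c` the standard-normal coefficient along the (centred, normalised)
kernel direction and `Q ~ chi-squared(N-2)` the residual sum of squares on
the orthogonal complement,

    T = N log1p(c² / Q)   if c > 0,   else 0.

Sampling `(c, Q)` is distributionally identical to generating 49-pixel noise
windows and evaluating the statistic, at a small fraction of the cost;
windows with `c < 0` contribute exact zeros and are only counted.  The
`n_mc ≥ 100/p` requirement keeps ~100 samples beyond the estimated quantile.
A test verifies the sampler's cutoff against the statistic evaluated on
actual simulated windows.

**Candidates, fitting, depletion.**  Candidates are strict local maxima of
the score map.  Each is fitted by bounded Levenberg–Marquardt over
(x, y, amplitude, background) with sigma fixed and the position constrained
to ±1 px of the candidate; the fitted spot model is subtracted from a
working image and detection repeats until no candidate passes (serial
depletion), which recovers spots at high spatial density.  Accepted spots
are never closer than 1 px (duplicate suppression); fitting order within a
round is brightest-first with row-major tie-breaks, so output is
deterministic.  Spots within `window_half` of the image border are
undetectable by construction.

**Close pairs: conditioning and deblending.**  Two refinements handle spot
pairs near the resolution limit, both preserving the calibrated
false-positive rate because every accepted spot must clear the full cutoff
in its own window *conditional on the other fitted component being
subtracted* — exactly the bar that depletion applies across rounds:

1. *Screening at half the cutoff.*  For a near-equal pair ~3 px apart, each
   member's window contains the other spot, which inflates the H1 residual
   and depresses both unconditional scores; candidates are therefore
   screened at `cutoff/2` and accepted only on the conditional statistic.
2. *Two-spot deblending.*  When a single-spot fit leaves a residual that
   still shows spot evidence anywhere in the window, the window is refitted
   jointly with two spots (on an enlarged patch so the partner fits inside).
   A split is only accepted when the fitted separation exceeds `2·sigma`:
   below the Sparrow limit two equal Gaussians produce no intensity dip and
   the decomposition is degenerate, so closer pairs are deliberately left
   merged.

The Sparrow limit sets a hard ceiling on recall benchmarks: with spots
placed uniformly at realistic densities (~500 per cell), 8–10% of spots have
a neighbour within `2·sigma` and each such pair can only ever be counted
once.

**3D counting.**  Z-stacks are detected per slice; detections in adjacent
slices within `link_radius_px` (default `2·sigma`) are merged by single
linkage through consecutive slices, each cluster contributing one 3D spot at
its intensity-weighted centroid.

## Single-fluorophore calibration and labeling density

Videos of sparse, surface-adsorbed probes under continuous excitation give
per-spot intensity traces (per frame, a linear amplitude/background fit at
the fixed spot position).  Single molecules photobleach in one discrete
step, so traces are classified single-molecule when changepoint detection
finds *exactly one downward step*, the post-step level is within 2 noise
standard deviations of background, and the pre-step plateau CV is below 0.5
(excluding multi-emitter and blinking-truncated traces).  Changepoints are
found by binary segmentation on the mean with a BIC-style penalty (default
`3 log n` on the `n log(RSS0/RSS1)` gain) — a deliberately simple method
that meets the recovery simulations (steps at SNR 8 located within ±2
frames in ≥95% of runs); any changepoint method with that property would do.

The pre-step plateau means form the single-fluorophore intensity
distribution.  Labeling density (fluorophores per transcript) is then each
FISH spot's fitted amplitude divided by the mean single-fluorophore
intensity — valid because the unit-mass PSF convention makes the amplitude
equal the spot's total photons.  The pipeline is scale equivariant:
rescaling all images rescales the calibration and leaves density estimates
unchanged.

## The synthetic data generator

The generator emulates the statistical structure of the real experiments,
not their optics in detail:

* **Transcripts** are placed uniformly in an elliptical cell mask; each
  carries `n ≥ 1` fluorophores drawn from a zero-truncated Poisson
  parameterised by its truncated mean.  The real distribution of probes per
  transcript is unknown (only means are measurable); zero truncation
  reflects that an unlabeled transcript is invisible.
* **Photophysics.**  Per-fluorophore intensities are Gamma distributed
  (mean, CV); bleaching is exponential with a per-fluorophore lifetime drawn
  once, so survival is monotone within a time-lapse; blinking is iid
  per-frame thinning.  Presets: `dye` (60 photons/frame, CV 0.25, bleach
  0.006/s ≈ 2.8 min mean emitting lifetime, no blinking; 425 spots/cell,
  mean 8.0 fluorophores), `qd13` (300 photons/frame, CV 0.15, photostable,
  on-fraction 0.8; 487 spots, mean 10), `qd17` (as qd13 but 75 spots, mean
  2.3 — the large-probe steric exclusion regime).  The photon yields encode
  the regime contrast that matters for detection: dye spots sit close to the
  autofluorescence shot noise, QD spots far above it.
* **Autofluorescence** is a Gaussian random field (FFT low-pass of white
  noise; mean 200 photons, s.d. 60, correlation length 40 px inside the
  cell), restricted to the mask with a Gaussian edge taper of sigma 6 px
  (~1 µm at 160 nm pixels).  The taper models the fall-off of cell body
  thickness near the adhesion edge; a hard step at the mask boundary would
  be unphysical and would dominate detection behaviour at the cell rim,
  since no constant-background window model can absorb a step.
* **Camera** noise is Poisson shot noise × gain + Gaussian read noise +
  offset, rounded and clipped to the bit depth.  The EM-register excess
  noise of an EMCCD is absorbed into the Gaussian term — consistent with
  the Gaussian-noise assumption of the detection statistic, which is the
  quantity being validated.  Simulations default to 16-bit quantization.
* **Multiplexing.**  Emission spectra (synthetic Gaussian lines at 608, 693,
  800 nm) are split across bandpass filters (600/37, 698/70, 809/81 nm) by
  trapezoidal band integrals; channels are rendered and noised
  independently.  The three filter bands are disjoint, so per-channel
  analyses are independent and no spectral unmixing is performed.
* **Z-stacks** use 0.22 µm slice spacing and a Gaussian axial intensity
  profile (sigma 0.35 µm), so spots span 2–4 slices.

What the generator does *not* emulate: depth-dependent PSF aberrations,
nonspecific binding chemistry, QD power-law blinking statistics, real
EMCCD gain-register statistics, and 8-bit export quantization.  Passing
tests therefore demonstrate correctness of the *analysis* under its stated
noise model, not performance claims about any particular microscope.

## Determinism and numerics

Every generator takes one integer master seed; per-cell/frame/channel
sub-streams are derived by an integer fold, so outputs are bit-reproducible
and independent of generation order.  Degenerate inputs are defined rather
than left to chance: a constant window scores `T = 0`; a window fitted
exactly scores `Inf`; an all-constant trace has no steps; a single-threshold
sweep has an `NA` slope; zero-variance 2D/3D comparisons are flagged
degenerate.  Spot rendering uses a ±8 sigma support so that the omitted tail
(<1e-14 of the amplitude) is negligible against the 1e-9 photon-conservation
tolerance checked in the tests.  Score maps subtract the frame mean before
forming sums of squares to avoid cancellation at large camera offsets.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at sizes a laptop handles in
minutes, chosen to keep Monte-Carlo error well inside each tolerance:
noise-frame calibration uses 500 frames of 512×512 at 10 and 20 dB with the
minimum compliant `n_mc`; threshold sweeps and photostability series use
256×256 cells (half-scale presets with spot counts scaled by area to
preserve density, 5–7 cells per condition); detection-accuracy and
labeling-density analyses use full 512×512 fields with ~500 spots.  The
acceptance script prints each quantity with the problem size it used.

## Known limitations

* Sub-Sparrow pairs (separation < 2·sigma) are intentionally counted once;
  at ~500 spots per cell this biases raw counts ~3–5% low.  Real data has
  the same physics.
* The chi-squared mapping is conservative in the far tail; use
  `calibration_mode = "monte_carlo"` when absolute false-positive rates
  matter.
* The GLRT's constant-background model loses power where the background
  curves strongly within a window (residual effect at cell edges even with
  tapered autofluorescence).
* Step detection assumes piecewise-constant traces; heavy blinking
  (sub-frame flicker) biases single-fluorophore intensities low.
* The 3D linker merges spots that overlap in xy across consecutive slices;
  axially aligned distinct molecules closer than the axial spread merge.
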