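---
title: "Quantifying egg camouflage in visible and ultraviolet imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg camouflage in visible and ultraviolet imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcamo)
```

`nestcamo` quantifies how well eggs in open ground nests match their
surroundings, as seen by predators with different visual systems, and how
that match degrades as sun-exposed eggshells fade. It covers the full
measurement chain — camera digital numbers to calibrated reflectance, to
predator cone catches, to a texture-based camouflage score — plus a
synthetic scene generator that makes the whole chain testable end to end
without field imagery.

## The measurement model

**Reflectance calibration.** Scenes are photographed in two passes: a
3-channel visible exposure (400–700 nm) and a 1-channel ultraviolet
exposure (350–400 nm), assumed pixel-registered (tripod, sequential
filters). The camera applies an unknown monotone transfer function; we
model it per channel as a power law with black level,
`DN = black + gain * R^(1/gamma)`. `linearize()` inverts it, and
`normalize_to_reflectance()` divides each channel by the mean linear value
over an in-frame grey standard of known 25% reflectance:
`R(p) = 0.25 * L(p) / mean(L over standard)`. Two properties make this
robust and testable: the result is invariant to global exposure changes,
and normalising twice changes nothing. Saturated pixels are flagged and
excluded from both the standard mean and region means — reflectance is
undefined there; values above 1 are retained, since specular pixels can
legitimately exceed the standard. The real linearisation in the field
lives inside the camera-specific raw pipeline; what is testable at desk
scale is the contract that decode inverts encode, which the test suite
checks on ramps (to ~1e-6 without quantisation, to the 16-bit quantisation
floor with it) and on full scenes (eggs recovered within 1%).

**Regions.** All masks come from closed polygons in 0-based pixel
coordinates (x right, y down) rasterised by the pixel-centre rule — a
pixel belongs to a region when its centre is inside the polygon. The rule
is deterministic and is checked against a brute-force point-in-polygon
scan in the tests. Egg colour is summarised as the mean over the egg
polygon of the per-pixel mean of R, G and B (the VIS band set) and of the
UV channel (the UV band set).

## Predator visual models

Camouflage is evaluated after mapping reflectance images into the
cone-catch space of four observers: a dichromatic ferret (peaks 430,
538 nm), a trichromatic human (420, 533, 562 nm), a violet-sensitive
tetrachromatic peafowl (421, 457, 505, 566 nm) and an
ultraviolet-sensitive tetrachromatic blue tit (371, 448, 503, 563 nm).
Receptor sensitivities are built from the standard A1 visual-pigment
alpha-band nomogram template, peak-normalised on a 350–700 nm, 1-nm grid.
The beta-band is omitted: with all peaks at 371 nm or above and the grid
cut off at 350 nm its contribution is secondary, and only peak wavelengths
are specified for these observers. The human observer goes through the
same nomogram machinery rather than CIE colorimetric functions, for
uniformity across observers.

Four camera bands cannot pin down a full spectrum, so the bridge is
deliberately the simplest documented one: a piecewise-constant spectrum
over the nominal band supports (UV on 350–400, blue 400–500, green
500–600, red 600–700 nm), with band-edge values set to the mean of the
adjacent bands so that trapezoid integration of step spectra is exact.
Quantum catches are `Q = ∫ R(λ) S(λ) I(λ) dλ`, and each channel is
divided by the catch of the flat 25% grey standard under the same
illuminant (von Kries normalisation), so a spectrally flat scene maps to
1.0 in every channel of every observer regardless of the illuminant. The
default illuminant is equal-energy; a Planckian 6504 K daylight
approximation is available (`illuminant_daylight()`) since the field
illuminant was not recorded. Ocular-media transmission is not modelled;
it would enter as one more multiplicative curve in the catch integral.
Because the reconstruction is linear in the four band values, the mapping
is exactly a 4 × chromacy matrix per observer — the package exploits this
for speed, and a test asserts the equality against the per-pixel
integral route.

## Texture signatures and the camouflage score

Texture is measured with a 56-kernel bank: at each scale σ ∈ {16, 32, 64,
128} px, five odd-symmetric and five even-symmetric Gaussian-derivative
kernels at orientations {0, 36, 72, 108, 144}° (five samples evenly
spaced over [0, 180), endpoint excluded to avoid duplication), plus two
Gaussians and two Laplacians of Gaussian at σ and √2σ — the √2 ladder
mirrors standard texton banks, which specify only "two" of each. The
oriented kernels are isotropic directional derivatives in steerable form
(cosθ·Gx + sinθ·Gy, and the three-term second-derivative analogue), so
every kernel is a short sum of separable terms; convolution runs as a few
1-D passes per scale (as banded-matrix products, fast under BLAS) and
equals direct 2-D convolution with the returned kernels to rounding. This
choice trades the elongated anisotropic kernels of some texton banks for
exactness and speed; the response space spans the same orientation
information up to the steering rank. Support is truncated at ±3σ of each
kernel's largest constituent σ; borders use mirror padding, avoiding the
dark-frame artifacts that zero padding would inject into regions near the
image edge. Convolving every channel of a C-channel cone-catch image
yields C × 56 response images (168 for a trichromat).

Per-pixel response vectors over the analysis region are standardised
(zero mean, unit variance per feature — responses across σ = 16…128 px
differ in magnitude by orders of magnitude, and unstandardised clustering
would be dominated by the coarsest scale) and clustered with K-means into
k = 20 texture centres (`stats::kmeans`, Lloyd, k-means++ seeding, 10
restarts, best within-SS kept). The vocabulary is fitted per image on the
union of the egg and microhabitat pixels: the method compares regions
within a single photograph, so a per-image vocabulary is consistent and
avoids cross-scene calibration questions. On large regions the restarts
run on a seeded 1,500-pixel subsample and the winning centres are refined
by one full Lloyd pass on a 6,000-pixel fit sample before all pixels are
labelled; the fit is deterministic given its seed. Each pixel is labelled
with its nearest centre (Euclidean distance in the standardised space,
ties to the lowest centre index — checked against an exhaustive oracle).

The camouflage score compares the normalised label histograms ("texture
signatures") of (a) the union of the egg polygons and (b) a 45-cm
diameter disk centred on the nest, minus the egg pixels — excluding the
eggs from their own comparison region — using the χ² histogram distance
½ Σ (h₁−h₂)²/(h₁+h₂), with empty bins skipped. The score is symmetric,
zero iff the signatures are equal, and bounded by 1 (disjoint supports).
Lower is better camouflage. Absolute values depend on k, the bank and the
region sizes, so only within-study comparisons (day 0 vs day 7, model vs
model) are meaningful; field reports on other scales (e.g. unnormalised
or per-channel-aggregated variants) are not comparable number-for-number,
and this package makes no attempt to match any particular absolute scale.

## The synthetic scene generator

The generator emulates the two field experiments with known ground truth.
A scene is a 4-band reflectance image containing: band-correlated
Gaussian-blob clutter (smoothed white noise at a configurable grain size
and contrast, 70% of clutter variance shared across bands) around a base
soil tone; 1–10 egg ellipses (3.3 × 2.5 cm) with darker maculation disks
covering a target fraction of the egg area (default 0.25, placed with an
accept-if-closer rule so the realised fraction tracks the target); a
square 25%-reflectance grey standard; Gaussian pixel noise (SD 0.004
reflectance units); and region annotations that exactly delimit eggs and
standard, because the painted masks are the rasterisations of the
returned polygons. Egg layout, maculation and clutter depend only on the
scene seed, so the same nest keeps its eggs across days; pixel noise is
re-drawn per day, as a fresh photograph would be. Each egg gets a small
correlated brightness offset (SD 0.008) standing in for between-female
variation.

Default egg colours put the day-0 egg mean at 0.175 (VIS) and 0.124 (UV),
split between ground colour (0.28, 0.20, 0.13, 0.145) and spots (0.12,
0.09, 0.06, 0.06) at spot fraction 0.25 — the observed starting points of
commercial quail eggs.

**Fading.** Eggshell fading is modelled as linear-with-cap in cumulative
normalised dose: `out = min(in + slope·dose, cap)`, with dose 1 defined
as seven days under direct sun and separate doses for the VIS bands
(scaling with visible irradiance) and the UV band (scaling with UV
index), since the two fade at different rates per unit of their
respective radiation. The linear form follows from the near-perfect
linear correlation between reflectance change and received radiation in
the field data; the default slopes (0.186 per VIS band, 0.089 UV) are
calibrated once so that one unit of dose reproduces the observed direct-sun
week: VIS 0.175 → 0.361 (+106%), UV 0.124 → 0.213 (+71%). The cap (0.95)
keeps faded reflectance physical; it is not reached under the default
designs. Band-wise linear fading is a phenomenological stand-in — no
pigment photobleaching chemistry is modelled, and the spectral coupling
between bands that real protoporphyrin/biliverdin bleaching would induce
is absent.

**Radiation.** The five shading treatments (direct sun, 1/2/4 white cloth
layers, 1 black layer) are encoded as transmittances anchored to the
recorded averaged daily maxima (730/224/160/97/7 W m⁻² and UV index
7.5/2.3/1.6/1.0/0.1). Simulated records sample every 5 minutes over a
12-hour window (145 points/day) under a half-cosine diurnal bell — only
the daily maximum matters downstream — with a 2% lognormal day-to-day
weather factor. Summaries take the maximum within each day, then average
across days.

**What passing tests do and do not show.** The generator produces scenes
whose statistics (clutter spectrum, egg geometry, noise) are idealised;
passing the end-to-end suites shows the measurement chain and the
camouflage metric behave correctly under known ground truth and that the
documented qualitative patterns (dose–response linearity, camouflage
degradation under all four observers) emerge from the modelled mechanism.
It does not validate the fading law's functional form against chemistry,
nor the metric's absolute scale on real nests.

## Experiment replications and problem sizes

`run_experiment1()` renders one ten-egg scene per treatment (rows of
3/4/3), photographs it on days 0, 3 and 7 through the synthetic camera,
recovers reflectances via the grey standard, and reports per-treatment
percent changes and their Pearson correlations with the radiation
summaries. `run_experiment2()` renders three-egg nests under direct-sun
fading, maps each calibrated scene to the four observers and scores
camouflage per nest × day × model, then summarises day-wise means ± SE
(nest as the unit) and flags whether camouflage worsened; formal
inference is delegated verbatim to `nlme::lme(chi2 ~ factor(day),
random = ~1 | nest)`, the model family used for such repeated-measures
designs, and never re-implemented.

Desk-scale defaults: scenes at 5 px/cm (the 45-cm microhabitat disk is
225 px across, images 300² px) with the filter bank at
`scale_factor = 0.25` (σ = {4, 8, 16, 32} px), 7 nests, days 0 and 7.
These sizes keep a full experiment-2 replication to a few minutes on one
CPU while leaving every kernel comfortably inside the image; the bank is
geometrically similar to the full-scale one, so scores relate across
scales qualitatively, not numerically. The full-scale profile (10 px/cm,
σ = {16, …, 128} on larger frames) uses the same code paths.

Within a scene, the four observers' feature matrices are exact linear
recombinations of the four band response stacks (cone catches are linear
in the bands; convolution is linear), so the bank is applied once per
scene and recombined per observer — a pure speed-up whose equality with
the reference path is asserted in the tests.

## Numerical choices and degenerate inputs

- Derivative kernels are exactly zero-sum (antisymmetry for odd; the 1-D
  second-derivative kernel is de-meaned before use for even/LoG), so flat
  fields produce strictly zero texture response.
- Nearest-centre ties break to the lowest centre index; K-means restarts
  and subsampling are driven by one seed, and every pipeline stage
  derives child seeds from the master seed, so runs are bit-reproducible.
- Histograms entering the χ² distance must be normalised within 1e-6;
  empty bins are skipped (their contribution is 0/0 → 0).
- Degenerate inputs fail loudly with classed errors: geometry that does
  not fit the frame, an empty rasterised polygon, too few unsaturated
  standard pixels (< 100), fewer masked pixels than k, zero-variance
  inputs to the correlation, incomplete design tables (the missing
  treatment × day × band combinations are listed).
- Reflectances above 1 are kept in images, but clipped to 1 (with a
  warning) by `arcsine_sqrt()`, whose domain is [0, 1].

## Known limitations

Fading is band-independent and linear; real photobleaching saturates and
couples bands. The spectral bridge is piecewise-constant; a trained
band-to-cone regression would be better where calibration spectra exist,
and the operation boundary (`reconstruct_spectrum()`) is designed to be
swappable. VIS/UV registration errors, vignetting and flat-field
variation are not modelled. Scores are comparable only within a
vocabulary (per image); cross-image comparisons rely on the day-wise
summaries, matching how the field design is analysed.
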