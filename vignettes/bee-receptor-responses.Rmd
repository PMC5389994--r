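---
title: "Modelling bee photoreceptor responses to multispectral floral scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bee photoreceptor responses to multispectral floral scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beefield)
```

## The question the package addresses

Bees are trichromats, with photoreceptors peaking in the UV (S, ~344 nm),
blue (M, ~436 nm) and green (L, ~544 nm), yet they rely almost exclusively
on the long-wavelength channel for edge detection, motion vision and
target detection at low resolution. One adaptive explanation is that the
L channel delivers the most *reliable* signal when viewing natural
objects: within a petal or a leaf, per-pixel L responses vary least
relative to their mean, so grouping pixels into objects is easiest in
that channel. `beefield` implements the full modelling chain needed to
quantify that claim on multispectral (340–700 nm, seven-band) images of
flowers: a physiological receptor model, an image-calibration pipeline,
per-region response statistics, a Monte-Carlo factor sweep that isolates
*why* the L channel wins, and a synthetic scene generator that makes the
whole chain testable without an external image database.

## The receptor model

Three steps take a reflectance spectrum to a receptor response.

**Quantum catch.** For stimulus reflectance $I_s(\lambda)$, receptor
sensitivity $S(\lambda)$ and illuminant $D(\lambda)$,

$$P = R \sum_{\lambda} I_s(\lambda)\, S(\lambda)\, D(\lambda),$$

summed over the shared wavelength grid. All spectra live on one grid (by
default the seven filter peaks, one point every 60 nm), so the integral
is a plain sum; the grid-spacing factor is omitted because it cancels
between this sum and the background sum below.

**Von Kries adaptation.** The sensitivity factor is the reciprocal
background catch,

$$R = 1 \Big/ \sum_{\lambda} I_B(\lambda)\, S(\lambda)\, D(\lambda),$$

where $I_B$ is the background the receptor is adapted to. Each receptor
rescales its gain independently in its own spectral domain, which makes
every response invariant to rescaling the illuminant (tested to 1e-12)
and anchors the background itself at $P = 1$.

**Response nonlinearity.** The dimensionless response is the hyperbolic
(Naka–Rushton-type) transform $E = P/(P+1) \in [0, 1)$, exactly 0.5 at
the adaptation background. Implementation detail: pipeline paths compute
$P$ as a ratio of two catches accumulated in an identical operation
order, so a stimulus bitwise-equal to the background yields $E = 0.5$
*exactly*, not merely to rounding error.

## Receptor sensitivities

Measured bee sensitivity curves are not redistributable here, so the
default `bee_receptors()` builds them from the Govardovskii A1
visual-pigment alpha-band template, which captures the property that
matters for the SNR analysis: pigment absorbance curves broaden (in nm)
as their peak moves to longer wavelengths. A Gaussian beta band centered
at 340 nm (SD 25 nm) is added with amplitude `beta_fraction`; bee
receptors show a secondary UV peak that grows with the main peak's
wavelength, so the default schedule `default_beta_fraction()` rises
linearly from 0 at 344 nm to 0.25 at 544 nm. The growth with peak
wavelength is deliberately encoded in this schedule rather than inside
`template_sensitivity()` itself, keeping the template a pure two-parameter
primitive. Total sensitivities (the summed sensitivity across all
wavelengths) are held constant relative to each other via
`normalize_total()`; the default weights are 1:1:1 and everything is
overridable from CSV (`read_receptor_csv()`).

The packaged D65 illuminant is the standard CIE tabulation at 10-nm
steps, resampled on load; absolute scale is irrelevant under von Kries
adaptation. The packaged green-leaf background is synthetic (UV-dark,
green bump, chlorophyll dip, red-edge rise) and is only a fallback: the
pipeline's default adaptation background is the mean of the leaf regions
actually present in the analyzed image set, shared across all images of
a run (`adapt_per_scene = TRUE` re-derives it per image).

## The image pipeline

Stacks are seven co-registered grayscale images (PNG/TIFF, 8- or 16-bit,
mapped to [0, 1] by the type maximum) listed in a YAML manifest together
with the gray-reference rectangle and optional region masks.

**White balance** uses the in-frame gray reference only: per band, the
darkest and lightest pixel values inside the rectangle map affinely to 0
and 1 (clipped). Pixel values are thereafter treated as linear
reflectance; no gamma decoding is applied, since a two-point gray-scale
correction says nothing about intermediate nonlinearity.

**Band alignment** is translation-only at integer precision, by
exhaustive normalized cross-correlation within `max_shift` pixels
against the band nearest 520 nm (mid-spectrum, typically the strongest
reflectance signal). The correlation is computed template-style: the
moving band's central crop (margin `max_shift`) is held fixed and
correlated against the implied reference window. Computing plain
overlap correlations instead would compare windows of different content
across candidate shifts, and a wrong shift whose window happens to
retain more high-variance content (e.g. more of the gray scale) can
then outscore the true one — a bias we observed and designed out.
Ties resolve to the smallest displacement; a best shift on the window
boundary logs a residual-misalignment warning; constant bands are left
unshifted with a warning. Alignment never alters pixel values, only
positions; pixels translated in from outside the frame are zero-filled
and excluded via the stack's validity mask.

**Region sampling** draws 1000 pixels per region by default, without
replacement when the mask is large enough, with replacement otherwise
(flagged and messaged — flower centers are often smaller than 1000 px).

**Renderings**: false color maps bands near 640/520/460 nm to RGB
("human") or 580/460/340 nm ("bee": UV becomes blue, blue green, yellow
red); heat maps scale $E$ linearly to 8 bits (round half up);
`downsample_ommatidia()` averages the image over an aspect-preserving
grid of ~5000 blocks, the approximate facet count of a honeybee eye.

## Region statistics

For each region we report both the response to the region's *mean*
spectrum (describing its color as the bee sees it) and the moments of
*per-pixel* responses; the two differ under the nonlinearity (Jensen's
inequality), and both paths are exposed. The signal-to-noise ratio is
the mean of per-pixel responses divided by their standard deviation — a
within-object homogeneity measure, not a photon-noise quantity. All SDs
use the population convention (divisor $n$), stated in the output; the
source literature is ambiguous between SD and standard error for the
SNR denominator, and we follow the SD definition without silently
reconciling the two. Zero-variance regions yield an infinite SNR, which
is flagged, excluded from aggregation, and counted.

Channel comparisons use `stats::kruskal.test` across the three
receptors' per-species SNR samples and pairwise `stats::wilcox.test`
signed-rank tests paired by species, requiring at least five species. No
multiple-testing correction is applied by default (none is standard in
this literature's figure captions); `adjust = "holm"` enables one.

## The null-model factor sweep

`factor_table()` crosses four binary factors: illumination (unit vs
D65), background (unit vs average leaf), sensitivity shape (unit vs
template) and reflectance source (random vs petal spectra), running each
of the 16 configurations over seven candidate peak wavelengths. "Unit
sensitivity" is interpreted as a one-hot indicator at the peak band, not
an all-ones curve: an all-ones sensitivity would make every peak's
response identical by construction, and the sweep could not show how
responses track the reflectance at the peak — which is precisely what
the null model on petal spectra is meant to exhibit. Template-mode
sensitivities are normalized to unit total so the totals stay constant
across peaks in both modes. Random reflectance spectra are i.i.d.
Uniform(0, 1) per band (the distribution is a free choice; a Beta
option exists for robustness checks), and whether real spectra are
spectrally correlated across bands is deliberately not modelled here.

With all factors at unit, mean responses are flat across peaks (the
Monte-Carlo flatness is about 0.5% at 10,000 spectra, comfortably inside
the 1% bound the tests assert). Feeding petal spectra whose means rise
with wavelength makes mean quantum catches rise strictly with peak
wavelength, and the hyperbolic transform compresses the across-peak
spread of $E$ well below that of $P$ — the package's tests verify both,
plus the coefficient-of-variation contract $CV_E \le CV_P$ wherever
$\bar P > 1$.

## The synthetic scene generator

Scenes are schematic flowers — a petal annulus around a center disc on a
leaf background — plus a gray-reference strip, with full ground truth
(true reflectance cube, per-band gains/offsets/shifts, masks, region
mean curves). The generator encodes the reflectance regularities the
analysis assumes:

* every region's mean reflectance is nondecreasing with wavelength;
* petals are brighter than leaves and centers at every band, while
  leaves and centers are darkest in the UV/blue;
* per-band pixel noise never decreases with wavelength, and petals are
  by far the most homogeneous region;
* species-level variability of petal color is widest at short
  wavelengths (the `uv` jitter term), mirroring how flower colors
  spread out in the bee's color space.

Default mean curves are linear in wavelength: petal 0.15 → 0.80, leaf
0.07 → 0.47, center 0.05 → 0.43 across 340–700 nm. The petal UV level
was set deliberately low: real petals mostly absorb UV, and published
mean petal responses are nearly equal across the three receptors
(~0.68–0.70), which a UV-bright petal cannot reproduce — an early draft
with petal UV reflectance of 0.40 saturated the S channel and inverted
the petal SNR ordering. Pixel noise SDs interpolate linearly from
0.025→0.035 (petal), 0.04→0.09 (leaf), 0.05→0.10 (center). Noise is
independent Gaussian per band, truncated to [0, 1] by clipping — the
simplest model consistent with the monotone-SD structure; spatial
correlation, specular highlights, shading and botanical geometry are
*not* modelled, so passing tests demonstrate the pipeline's correctness
and the qualitative mechanism, not field realism.

The gray strip holds at least five flat-reflectance patches spanning
dark to light identically in every band. The patches are laid out in a
scrambled (non-monotone) order: a monotone staircase is nearly a ramp
along x, whose autocorrelation is too flat to pin down band alignment,
while the scrambled layout gives every band sharp high-amplitude edges;
the extreme patches also sit away from the strip ends so that band
shifts (edge-replicated in the generator) can never push the darkest or
lightest reference out of the reference rectangle. The strip itself is
noise-free, as a calibration target would be. Distortion is per-band
affine (gain 0.75–0.92, offset 0.02–0.08 by default), which the
white-balance step inverts exactly in memory and to within one 8-bit
quantization step after a file round-trip. Integer band shifts default
to ±3 px; the alignment-reference band (nearest 520 nm) is never
shifted, so recorded shifts are expressed in the reference frame and
alignment can recover them exactly.

## Numerical and design choices

* Interpolation is linear with no smoothing: the working grid has seven
  points, and higher-order schemes would add structure the data cannot
  support. Resampling is exact where the target grid is a subset of the
  source. Extrapolation is an error, never silent.
* The 60-nm grid is adequate for spectra varying on scales of ~100 nm
  or more (tested against a 1-nm oracle to within 5% in $E$); steep
  spectral features are outside what seven bands can represent.
* Degenerate inputs fail loudly: zero background catch (no spectral
  overlap), a gray reference with no dark–light span, an empty region
  mask, fewer than five species in a channel comparison.
* Seeds: every stochastic entry point takes an explicit seed, evaluates
  under it without disturbing the caller's RNG stream, and derives
  per-scene/per-region child seeds deterministically (kept below
  2^31).
* Problem sizes used by the test suite and acceptance script: 96×96-px
  seven-band scenes, 30 synthetic species, 1000 pixels per region,
  10,000 spectra per sweep configuration, 1000 replicates for the
  Wilcoxon power check.

## Known limitations

* Sensitivities are template approximations, not measured curves; users
  with measured data should load them via `read_receptor_csv()`.
* No ocular-media transmission, screening-pigment or self-screening
  corrections; no opponent coding or color-space modelling — the model
  stops at the receptor level.
* Alignment is integer-pixel and translation-only (no rotation, scale
  or subpixel registration), matching the template-matching approach
  used for scanned multispectral stacks.
* The exact relative total sensitivities of the three receptor classes
  are not publicly tabulated; only the 1:1:1 default is exercised by
  tests.
* Response maps serialize as 16-bit TIFF (the PNG writer available to R
  is 8-bit only), with scaling recorded in a JSON sidecar.
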