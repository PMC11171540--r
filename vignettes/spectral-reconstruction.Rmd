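---
title: "Reconstructing reflectance spectra from endoscopic RGB images"
author: "savehsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing reflectance spectra from endoscopic RGB images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savehsi)
```

## The problem

Narrow-band imaging improves the visibility of early mucosal lesions by
restricting illumination to the haemoglobin absorption bands near 415 nm
(the Soret band, absorbed by superficial capillaries) and 540 nm (a
secondary band reaching deeper vessels). `savehsi` emulates this without
narrow-band hardware: it reconstructs, for every pixel of an ordinary
8-bit sRGB endoscopy frame, a visible-range reflectance spectrum on a fixed
380–780 nm grid at 1 nm (401 bands), and renders the narrow-band view from
the reconstructed spectrum.

The reconstruction is only as good as the calibration that ties the camera
to a spectrometer. This vignette explains the model, the choices behind its
defaults, and exactly what the synthetic validation suite does and does not
establish.

## Model

### Colorimetric front end

sRGB codes are declared either 8-bit (0–255) or unit scale — the scale is an
explicit argument, never guessed — and linearised with the standard sRGB
transfer function (linear segment below 0.04045, power 2.4 above). Linear
RGB maps to CIE 1931 XYZ through the fixed sRGB (D65) matrix, scaled to the
0–100 luminance convention. Spectrometer-side tristimulus values use the
rectangle rule on the 1 nm grid,

$$X = k \sum_\lambda S(\lambda)\,R(\lambda)\,\bar{x}(\lambda), \qquad
  k = \frac{100}{\sum_\lambda S(\lambda)\,\bar{y}(\lambda)},$$

so that a perfect reflector has $Y = 100$ under the fitted illuminant. The
normaliser $k$ depends only on the illuminant and $\bar{y}$. The embedded
CIE 1931 2° observer and D65 tables are the published 10 nm tables,
linearly interpolated to the grid; at the smoothness of these functions the
interpolation error is far below every tolerance used in the package
(integrating a perfect reflector reproduces the published D65 white point
to about 0.1 on the 0–100 scale). The rectangle rule is appropriate because
the grid is dense and uniform.

The illuminant is a required configuration item with a D65 default. An
endoscope's lamp is not D65; when its spectral power distribution is
available it should be loaded via `read_spectrum_csv()` or
`resample_to_grid()` and passed to `patch_measurement_set()`. Calibration
and conversion always use the same illuminant, which is stored in the
serialized model.

### Camera-error correction

Real endoscope cameras deviate from the ideal colorimetric observer through
dark current, channel crosstalk, colour shift and nonlinear response. The
correction stage absorbs these with a polynomial regression in XYZ: each
camera-derived tristimulus vector is expanded into a variable vector $V$ of
monomials, and the correction matrix is the least-squares solution

$$C = XYZ_{\mathrm{spectrum}} \cdot \mathrm{pinv}(V), \qquad
  XYZ_{\mathrm{correct}} = C\,[V].$$

The default expansion has 14 terms: a constant (dark-current offset), the
linear terms (crosstalk/colour shift), all six degree-2 monomials, $XYZ$,
and the pure cubes (nonlinear response). The composition is configurable
through `expansion_spec()`; the linear terms are mandatory because they
carry the identity part of the correction. With 24 patches and 14 terms the
system is overdetermined; fewer patches than terms is a hard error — the
package never regularises silently — and a rank-deficient design matrix is
likewise an explicit error.

### PCA basis and spectral synthesis

Reference reflectance spectra of natural and tissue-like surfaces are
smooth and highly correlated, so a handful of principal components explains
almost all their variance. The basis stage runs mean-centred PCA
(`stats::prcomp`) on the reference spectra and keeps the smallest number of
components $k$ reaching a cumulative explained-variance target (default
0.999, capped at $k_{\max} = 12$; both configurable). The transformation
matrix regresses scores on the expanded corrected tristimulus values,

$$M = \mathrm{Score} \cdot \mathrm{pinv}(V_{\mathrm{color}}),$$

and a pixel's analog spectrum is synthesised as

$$S_{\mathrm{spectrum}} = \bar{R} + EV \cdot M \cdot [V_{\mathrm{color}}].$$

Two deliberate choices here. First, the synthesis adds the mean spectrum
back: PCA scores are defined about the mean, and without re-adding it even
the training set could not be reproduced exactly. Second, $V_{\mathrm{color}}$
defaults to the same 14-term family as the correction stage — the natural
reading of "all XYZ combinations" up to cubic order — and is independently
configurable.

Reconstructed reflectance is clipped to $[0, 1.2]$ rather than $[0, 1]$:
regression overshoot above 1 is diagnostic information (it usually flags
specular highlights or out-of-gamut pixels), and the number of clipped
samples is recorded on the result instead of being silently flattened.

### Numerical choices

* Pseudo-inverses use a rank-revealing SVD with relative tolerance
  $10^{-10}$; singular values below that fraction of the largest are
  treated as zero, and falling below full rank is an error, not a silent
  truncation. The default expansion mixes magnitudes (a constant next to
  $X^3 \sim 10^6$ on the 0–100 scale); the observed condition numbers on
  24-patch fits stay well inside the tolerance.
* Serialized models (`save_calibration()`) are a single versioned JSON
  archive with numbers written at 17 significant digits, which round-trips
  IEEE doubles exactly.
* Whole-image conversion processes rows in chunks (`chunk_rows`) and pixels
  in fixed-size internal blocks, so memory stays bounded; the result is
  identical for every chunking, and the test suite checks bit-identity.
* ENVI output is band-sequential with a plain-text header; `float64` mode
  round-trips byte-exactly, `uint16` mode scales $[0, 1.2]$ onto 0–65535
  (half-step maximum error).

## The synthetic validation world

No clinical images or real calibration measurements ship with the package,
so the validation suite builds its own world with three generators.

**Patch spectra.** `synth_patch_spectra()` emulates a 24-patch reflectance
target as `mean + deviation` with the deviation in an exactly
`basis_dim`-dimensional span of smooth curves, values kept inside
[0.02, 0.95] by scaling (never clipping). The span is built for
*identifiability from tristimulus values*: three broad raised-cosine
components carry independent seeded coefficients and determine a patch's
XYZ; components beyond the third are smooth metameric blacks — projected to
integrate to zero against $S\bar{x}$, $S\bar{y}$, $S\bar{z}$ — whose
coefficients are seeded degree-2 polynomials of the three primary
coefficients. The score-from-XYZ map of such a set is a degree-2 polynomial
inside the default expansion span. This structure is not a convenience: a
reflectance component that is both invisible to the observer and
statistically independent of the visible components is unrecoverable from
RGB by *any* algorithm, so a generator with generic independent
coefficients in more than three dimensions would make exact recovery
impossible in principle. Coupling the hidden dimensions to the visible ones
is the property that real smooth reflectance families have and that makes
spectral reconstruction from three channels work at all.

**Camera.** `simulate_camera()` integrates spectra against channel
sensitivities (default: the CMFs, so the undistorted camera is exactly
colorimetric), then applies, in order, the sensor nonlinearity, channel
crosstalk, dark-current offset (in 1/255 "count" units), seeded Gaussian
noise, optional sRGB encoding and optional 8-bit quantization.
`ideal_srgb_camera()` sets the crosstalk to the XYZ-to-linear-sRGB matrix
so the quantized output is an ordinary 8-bit sRGB rendering. The
nonlinearity is specified *inversely*: `cubic_distortion()` gives the
monotone per-channel cubic that maps a camera reading back to the scene
value (default $0.92u + 0.25u^3$ on the XYZ/100 scale), and the simulator
inverts it numerically. Specifying the inverse keeps the map the correction
stage must learn exactly inside the polynomial span — the forward response
of a polynomial correction is not itself polynomial.

**Phantom.** `make_phantom()` builds a mucosa-like smooth background
spectrum with seeded sinusoidal vessel paths whose spectra are the
background attenuated by Gaussian dips at 415 and 540 nm with configurable
depth. It is a geometric/spectral test scaffold, not a biophysical
haemoglobin model: no scattering, no depth-dependent path length, no
oxygenation dependence.

### What the suite establishes (study conditions)

With 24 patches from a 6-dimensional basis, the in-span cubic distortion
and a noiseless continuous camera, the full calibrate-then-reconstruct loop
reproduces every patch spectrum and its tristimulus values to better than
$10^{-6}$ — the pipeline is exact when its assumptions hold exactly. Under
8-bit quantization, 2-count dark current and 0.5-count Gaussian noise, the
mean spectral reconstruction RMSE is about 0.003 and the pooled corrected
XYZ RMSE about 0.13–0.2 across seeds; training error is monotone in the
PCA dimension and in the expansion size, and the least-squares fits match
normal-equation solutions on small instances. On a 128 × 128 phantom the
415 nm band's vessel/background Michelson contrast exceeds the broadband
white-light contrast and grows monotonically with absorber depth.
Full-frame conversion is validated at 640 × 640 for chunking invariance and
lossless ENVI round-tripping; these sizes keep the whole suite inside a few
minutes on one CPU while exercising every code path at full spectral
resolution.

### What it does not establish

Passing tests on this synthetic world say nothing about: real endoscope
optics (the simulated distortions are low-order and in-span by
construction, real ones need not be); tissue spectra outside the smooth
low-dimensional family; metameric failures (two tissues with identical XYZ
under the calibration illuminant but different spectra are
indistinguishable after correction — the reconstruction returns one
spectrum per colour); specular highlights and colour-gamut clipping; or any
clinical detection performance. Evaluation is on training patches, matching
the calibration-procedure setting where the 24-patch target is the entire
measurable world; generalisation to unseen colours depends on the true
reflectance family being as low-dimensional and smooth as the target's.

## Display conventions and dataset utilities

The narrow-band composite routes the 415 nm band to display blue and green
and the 540 nm band to display red — a convention (documented, not a
formula from the physics) chosen to reproduce the reddish-brown mucosa and
dark vessel appearance of clinical NBI. Band windows are Gaussian with
30 nm FWHM by default, matching published narrow-band filter widths; only
the band centres are fixed by the technique. Per-band contrast stretching
uses the 1st–99th percentiles to resist specular highlights; a constant
band falls back to identity scaling with a warning.

The dataset utilities follow the object-detection conventions of the field:
Pascal-VOC XML corners (1-based, inclusive) become 0-based half-open pixel
boxes on read; YOLO labels store centre/size fractions; images resize to
640 × 640 by stretching or letterboxing (pad value 114/255). Dataset
splitting shuffles with a seed and cuts contiguously, sizes
$\lfloor n \cdot \mathrm{ratio} \rfloor$ with the remainder assigned to the
last partition; the default ratio is 70:15:15, and with a grouping key
(patient id) whole groups are assigned to the partition in which their
first shuffled item falls, so no patient ever straddles partitions.

## Known limitations

* One global correction per camera: no spatially varying (lens-shading)
  correction, exposure or white-balance estimation.
* The 1931 2° observer only; no chromatic adaptation transform between
  illuminants; no HDR input.
* Reconstruction capacity is bounded by the PCA dimension reachable from
  three colour channels through a polynomial map; spectra needing many
  XYZ-independent degrees of freedom will be projected onto the learned
  family.
* JPEG input is supported through the image reader, but calibration
  fidelity assumes the same compression pipeline for calibration and
  conversion images.
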