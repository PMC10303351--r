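---
title: "Methods: hyperspectral artery-vein analysis of fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral artery-vein analysis of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundushsi)
```

`fundushsi` classifies retinal vessel pixels as arterial or venous by
simulating a visible-band reflectance spectrum for every pixel of an RGB
fundus photograph and thresholding a principal-component projection of
those spectra. This vignette explains the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
phantom experiments can and cannot show.

## The physiological signal

Arterial blood is oxygenated; venous blood is not. Oxy- and
deoxyhemoglobin differ most in the red part of the visible band
(roughly 600–780 nm), where arteries reflect more light than veins, so
arteries look brighter and slightly more orange in fundus photographs
while veins are darker and wider. As diabetic retinopathy (DR)
progresses, arterial oxygen carriage degrades and the two spectra
converge, which is exactly why a classifier that works on normal retinas
loses sensitivity and precision in proliferative disease. The package
stages disease as normal, background DR (BDR), pre-proliferative DR
(PPDR) and proliferative DR (PDR).

## Vessel segmentation

The green channel is used because it carries the strongest
vessel/background contrast (red saturates, blue is dark and noisy). It
is filtered with a bank of complex Gabor kernels: a Gaussian envelope
times a sinusoid along the rotated x axis, with the orientation swept
over $[-\pi/2, \pi/2]$ in steps of $\pi/180$ — 181 kernels, endpoints
included (the two endpoint kernels coincide up to the sign of the
imaginary part, which the magnitude removes). Per pixel only the maximum
magnitude over orientations is kept. Vessels of either polarity are
ridges of this response map, so the map is rescaled to 0–255 over the
field of view (FOV) and binarized by the iterative-mean rule: start at
the global mean, then repeatedly set the threshold to the average of the
two group means. Pixels strictly above the threshold, inside the FOV,
form the vessel mask after connected components smaller than
`min_pixels` are dropped.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `f0` | 1/8 cycles/px | wave frequency across the vessel; ~8 px period matches 2–12 px vessels |
| `sigma_x` | 1.5 px | envelope width across the vessel |
| `sigma_y` | 3 px | envelope length along the vessel |
| `theta_step` | $\pi/180$ | orientation resolution (181 angles) |
| `halfwidth` | $\lceil 3 \max \sigma \rceil$ px | kernel support |
| `epsilon` | $10^{-3}$ gray | threshold convergence tolerance |
| `min_pixels` | 30 px | smallest surviving component; keeps a 2 px-wide capillary of length ≥ 15 |

Two defaults deserve justification. First, the envelope is
**anisotropic** ($\sigma_y = 2\sigma_x$): an isotropic envelope responds
almost as strongly one envelope-width *beside* a vessel as on it, and the
resulting masks come out systematically wider than the vessels (on the
phantoms this costs ~0.05 Dice). Elongating the envelope along the
vessel and narrowing it across is the standard oriented-ridge setup and
what the defaults use. Second, the threshold tolerance is $10^{-3}$
rather than half a gray level: the iterative-mean update is a
piecewise-constant map on discrete data, so with a tight tolerance it
reaches its *exact* fixed point in at most ~15 steps, whereas stopping
at 0.5 can halt more than a gray level short of the fixed point on
slowly converging histograms. A flat image is degenerate: the threshold
equals the common value, flagged, and segmentation returns an empty
mask.

Numerics: filtering is correlation (no kernel flip; the real kernel is
even and the imaginary odd, so the magnitude is flip-invariant),
computed by FFT on a reflection-padded image — the padding is at least
the kernel half-width, which makes the circular FFT product exact on the
interior, verified in the tests against a four-loop spatial correlation
to below $10^{-8}$. Reflection padding avoids the spurious dark-border
response that zero padding would inject into the threshold histogram.
Ties in the threshold split (value equal to the threshold) go to the low
group. Rasters are indexed (row, col); kernel x increases with column.

The paper-style pipeline leaves two points open that are settled here as
configuration: the Gabor bank runs on the **raw** green channel (no
contrast normalization; an option exists because uneven illumination on
real images may need it), and the binarization is applied to the **Gabor
response map**, not the gray image — the flow-diagram ordering — since
thresholding the raw green channel would select the bright background
rather than the thin bright vessels.

## Spectral reconstruction

Calibration uses a 24-patch color checker whose reflectance spectra on
the 380–780 nm grid (1 nm step by default; the step is configurable
because reconstruction bandwidth is not otherwise pinned down) are
known, together with their camera RGB. PCA of the patch spectra yields a
mean spectrum and six orthonormal eigenvector spectra — six components
capture essentially all variance of smooth reflectance sets while
leaving the 24-patch regression overdetermined. Each patch's spectrum is
projected to six coefficients, and a ridge-regularised least squares fit
maps the fixed 11-term polynomial expansion of patch RGB
$(1, R, G, B, R^2, G^2, B^2, RG, GB, RB, RGB)$ to those coefficients.
The polynomial expansion (rather than raw RGB) buys the regression a
little curvature at negligible cost; ridge defaults to $10^{-6}$, enough
to keep the $11\times11$ normal matrix invertible without visibly
biasing the fit. A pixel's spectrum is then
$\hat s = \bar s + V (M \phi(\text{rgb}))$, clipped to $[0,1]$.

PCA is fitted to the *calibration* spectra, not the scene: calibration
precedes any scene in the processing order, and the checker is the only
place where spectra are actually known. Eigenvector signs are fixed
(largest-magnitude loading positive) so results are reproducible across
BLAS implementations; rank below six raises an error rather than padding
the basis.

**What reconstruction can and cannot do.** RGB carries three numbers per
pixel; the basis has six coefficients. The regression therefore recovers
only the component of the spectrum predictable from colour. When scene
spectra truly lie in the basis span and the coefficient-to-RGB map is
linear, reconstruction is exact to machine precision (the in-span test
fixture). On arbitrary scenes, colours far outside the checker's RGB
cloud — vessel colours are, since the checker is not blood-coloured —
are extrapolations and can carry a common-mode spectral bias of the
order of 0.1–0.3 reflectance units. Crucially this bias is shared by
arteries and veins: the artery–vein *difference* spectrum, which is what
the classifier uses, survives reconstruction (the tests require
correlation above 0.5 with the true difference and preservation of the
red-band ordering). Absolute oximetry is out of scope for exactly this
reason.

## Artery-vein classification

Per stage, the reconstructed vessel-pixel spectra are projected onto
their first two principal components (the first axis is the "x-axis" of
the score plot; the second is kept for plotting only). Scores are
min–max normalized to $[0,1]$ using bounds recorded from the training
pixels; test pixels outside the training range are clamped, and the
training bounds are reused unchanged — no leakage. Which side of the
axis is arterial is *learned* from the labelled training means (PCA sign
conventions make a hard-coded side fragile), and the decision threshold
on normalized component 1 is, by default, the midpoint of the two
class-conditional training means — a reproducible stand-in for a
manually placed threshold. An alternative `f1_scan` method sweeps
thresholds in 0.01 steps and keeps the one maximizing the mean training
F1 of the two classes. Each severity stage gets its own model, since the
score geometry changes as the classes converge.

Labels are evaluated only on ground-truth vessel pixels: sensitivity and
precision denominators count the true artery (vein) pixels, keeping the
two formulas interpretable, while segmentation quality is reported
separately as Dice. Reported tables round to one decimal place.

## The synthetic phantom

The generator emulates the inputs the clinical pipeline consumes:

* a dark circular FOV (radius 0.46 of the image side) on a black frame;
* a branching tree of quadratic Bézier curves radiating from an
  optic-disc-like origin, arteries with half-widths 1.2–2.6 px, veins
  1.5× wider, i.e. full widths within the 2–12 px regime;
* vessel cross-sections with a flat lumen and Gaussian walls
  (sd 0.7 px), so lumen pixels carry the exact class colour — which
  makes noiseless recovery experiments exact — while edges blend into
  the background;
* colours rendered through a three-Gaussian camera model (peaks
  600/540/460 nm, sd 40 nm, flat illuminant, unit gain): the simplest
  model that makes RGB an informative summary of a spectrum;
* artery/vein spectra from a parametric hemoglobin-like model: a shared
  logistic red-edge midline with two absorption dips near 542 and
  577 nm, plus/minus half of a red-band logistic difference curve scaled
  by the stage's contrast (normal 1.0, BDR 0.6, PPDR 0.45, PDR 0.25),
  and a mild severity-linked depression around 495–570 nm common to both
  classes. The difference is pointwise proportional to the contrast
  scale, so it halves exactly when the scale halves, stays positive
  through the red band at every stage, and makes venous red reflectance
  rise with severity;
* additive i.i.d. Gaussian RGB noise, default sd 0.01, clamped to
  $[0,1]$.

The full-contrast difference amplitude (0.15 reflectance in the deep
red, about 0.075 in the rendered R channel) was chosen so that, at the
default noise level, the four contrast scales span easy-to-hard
classification — roughly zero expected error at normal through ~15% per
class at PDR — reproducing the clinical difficulty ordering with
measurable gaps between adjacent stages.

All generators are pure functions of their seed (the RNG state is saved
and restored around them), and ground truth (vessel mask, label map, FOV
mask, true spectra) is stored with every scene.

What the phantom does *not* model: lesions (exudates, hemorrhages),
uneven illumination, optic disc and fovea appearance, ocular media
scattering, vessel central light reflex, or a realistic sensor (Bayer
mosaic, quantization). Passing the phantom suite therefore shows the
pipeline's internal consistency and its behaviour under the modelled
degradations (noise, shrinking spectral contrast), not clinical
performance.

## Study sizes and determinism

The replicated study behind the recovery and trend checks uses 10 images
of 256×256 px per stage and replicate, split 70/30 at the image level
(avoiding pixel leakage between sets), with 10 replicate seeds in the
test suite and 5 in the acceptance script; pooled test confusion counts
per stage-replicate give the metrics. Segmentation recovery is measured
on the default noiseless 256 px phantom. Child seeds for images,
checker and splits derive arithmetically from the master seed and stay
below $2^{31}$. Reported experiment quantities are computed fresh on
every run; reruns with the same configuration are bit-identical.

## Known limitations

* Absolute reconstructed spectra inherit the checker-extrapolation bias
  discussed above; only spectral *contrasts* are trustworthy.
* The classifier is a single threshold on one projection axis: it cannot
  represent class boundaries that curve in score space, and pixels are
  classified independently (no vessel-level voting).
* Segmentation Dice around 0.8 on phantoms reflects a mask one to two
  pixels wider than the true vessel; applications needing exact vessel
  calibre should not use this mask for width measurement.
* The severity stages differ only in spectral contrast and a mid-band
  depression; real stage differences (neovascularisation, hemorrhage)
  are structural as well as spectral.
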