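# fundushsi

Pixel-level artery–vein analysis of retinal fundus photographs through
simulated hyperspectral imaging (HSI).

In diabetic retinopathy (DR), the oxygen saturation of retinal arteries
and veins shifts as the disease progresses, and with it the visible
reflectance spectrum of the blood column. `fundushsi` implements a
three-part pipeline that exploits this:

1. **Vessel segmentation.** The green channel of the RGB fundus image is
   filtered with an oriented Gabor bank — a Gaussian envelope modulated by
   a sinusoidal plane wave,

   ```
   g(x, y) = 1/(2π σx σy) · exp(−½ (x′²/σx² + y′²/σy²)) · {cos, sin}(2π f0 x′)
   x′ =  x cos θ + y sin θ,   y′ = −x sin θ + y cos θ
   ```

   evaluated at 181 orientations θ ∈ [−π/2, π/2]. Per pixel only the
   maximum magnitude response R(x, y) = maxθ √(Gr² + Gi²) is retained.
   The response map is binarized with the classic iterative-mean
   threshold (T ← (μ_low(T) + μ_high(T)) / 2, iterated to its fixed
   point) and small connected components are removed.

2. **Spectral reconstruction.** A 24-patch color checker with known
   reflectance spectra (380–780 nm) is photographed through the camera
   model; PCA of the patch spectra gives a mean spectrum plus six
   orthonormal eigenvector spectra, and a ridge-regularised regression
   maps polynomially expanded pixel RGB (11 monomials) to the six basis
   coefficients. Every vessel pixel then gets a simulated reflectance
   spectrum `mean + V (M φ(rgb))`.

3. **Artery–vein classification.** Per disease stage, the vessel-pixel
   spectra are projected onto their first two principal components, the
   scores are min–max normalized to [0, 1], and a scalar threshold on the
   first-component axis separates arteries (rendered red) from veins
   (rendered blue). Performance is reported per class as sensitivity
   (100·TP/(TP+FN)), precision (100·TP/(TP+FP)) and their harmonic mean
   F1.

Because clinical fundus images with ground truth are not freely
available, the package ships a **synthetic fundus phantom generator**:
a dark circular field of view containing a branching Bézier vessel tree
whose artery/vein colours are rendered from hemoglobin-like parametric
reflectance spectra. A per-stage contrast scale (normal 1.0, BDR 0.6,
PPDR 0.45, PDR 0.25) shrinks the artery–vein spectral difference to
emulate DR progression, which makes the classification measurably harder
stage by stage — the behaviour reported for the clinical method.

## Worked example

```r
library(fundushsi)

cam <- camera_model()
train <- phantom_fundus("normal", size = 256, seed = 1, cam = cam)
test  <- phantom_fundus("normal", size = 256, seed = 2, cam = cam)
train
#> <phantom_scene> 256x256, stage normal, 5209 vessel px (12.0% of FOV), seed 1

# 1. segment the test image and compare to ground truth
seg <- segment_vessels(test$image, fov = test$fov_mask)
seg
#> <vessel_segmentation> 8631 vessel px, threshold 121.55 (9 iterations)
dice_coefficient(seg$mask, test$vessel_mask)
#> [1] 0.806

# 2. calibrate the RGB -> spectrum transformation on a color checker
checker <- color_checker(cam, seed = 99)
basis <- fit_spectral_basis(checker, k = 6)
tm <- fit_transformation(checker, basis, ridge = 1e-6)

# 3. fit the stage's score model on one scene, classify another
cube_train <- reconstruct_cube(train$image, train$vessel_mask, tm)
model <- fit_score_model(cube_train, train$av_labels, stage = "normal")
model
#> <av_score_model> stage normal, threshold 0.643 (midpoint), artery on high side, n = 5209

cube_test <- reconstruct_cube(test$image, test$vessel_mask, tm)
pred <- classify_cube(cube_test, model)
av_metrics(pred, test$av_labels, stage = "normal")
#>    stage  class sensitivity precision       f1   tp  fp  fn
#> 1 normal artery    91.88620  88.70804 90.26915 2616 333 231
#> 2 normal   vein    88.80296  91.95682 90.35238 2641 231 333
```

A single held-out normal-stage image is classified with ~90% F1 for both
classes; pooling several training images (as `run_av_experiment()` does)
pushes the normal stage above 99% while PDR, whose artery–vein contrast
is four times smaller, drops to ~70% — severity strictly degrades the
separability, in the order normal > BDR > PPDR > PDR.

Plot helpers: `autoplot()` on a phantom scene or score model,
`plot_spectra()`, `plot_score_plot()`, `plot_metrics()`. `tidy()` and
`glance()` methods summarise fitted models. A thin command-line wrapper
with `simulate / segment / calibrate / reconstruct / classify / evaluate
/ run` subcommands is installed at `inst/cli/fundushsi`.

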