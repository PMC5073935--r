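---
title: "Quantifying abrupt pigment-pattern cutoff at the lesion border"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying abrupt pigment-pattern cutoff at the lesion border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

In the dermoscopic ABCD rule, the *B* (border) criterion scores how sharply
the pigment pattern of a melanocytic lesion terminates at its periphery.
Clinically the lesion is divided into a "virtual pie" of eight angular
sectors and each sector is graded by eye for abrupt cutoff — a tedious and
subjective procedure. This package replaces the eight-sector eyeballing with
a dense, objective scan of the whole border: texture statistics are computed
in small circular regions placed all the way around the lesion periphery,
and a support vector machine decides from those statistics whether the
lesion looks malignant.

## Pipeline

Given an RGB dermoscopy image and a binary lesion mask (from any external
segmenter; the package does not implement one), the stages are:

1. **Mask standardization** (`standardize_mask()`): complement (segmenters
   often emit negative masks), clipping of a symmetric margin of
   `p/2` percent per side (default `p = 10`), morphological opening with a
   disk of radius 2, and retention of the single largest 8-connected
   component near the image center. The published per-side clipping formulas
   are dimensionally inconsistent (they evaluate to `1 + 50w/p`, beyond the
   image for any `p < 100`); the corrected margin `dim * p / 200` is the
   default and the literal form is kept behind `literal = TRUE`.
2. **Boundary tracing** (`trace_chain_code()`): Moore-neighbor tracing from
   the topmost-leftmost lesion pixel, clockwise in image coordinates,
   emitting a Freeman chain code with symbols 0..7 increasing
   counter-clockwise (0 = E, 2 = N, 4 = W, 6 = S). The trace stops when it
   is about to repeat its initial move out of the start pixel, which closes
   every single-component mask including ones with 1-px necks.
3. **Shadow border** (`method2_inner_boundary()`,
   `method3_inner_boundary()`): the traced border is contracted inward by
   `r` pixels. Method 2 shifts every boundary point along its own unit
   vector toward the centroid; it fails on strongly concave lesions (points
   within `r` of the centroid, or many points collapsing together — the
   package raises a classed `abruptcut_degenerate_contraction` error and
   exposes the minimum point spacing). Method 3, the recommended one, scales
   the whole border by `s = 1 - r/rho` (`rho` = centroid distance of the
   starting point) and re-centers it, a similarity transform that cannot
   fold. On a circular lesion both constructions coincide with the analytic
   inner circle of radius `R - r`.
4. **Peripheral sampling** (`method_regions()`): circle centers are placed
   every `round(1.5 r)` chain-code pixels along the shadow border (so a
   radius-2 circle steps 3 pixels). Each disk is rasterized
   (center-in-disk test) and intersected with the lesion interior; empty
   intersections are skipped and counted. Method 1 (circles on the border
   itself, no intersection) is retained for comparison; it deliberately
   admits out-of-lesion pixels and underperforms. The inter-circle spacing
   for method 1 is not stated in the source; the `1.5 r` rule is reused.
5. **Texture statistics** (`compute_glcm()`, `glcm_homogeneity()`,
   `region_mean_std()`): per region, a gray-level co-occurrence matrix at
   offset `(dx, dy) = (1, 0)` with `L = 8` levels, its homogeneity
   `sum p(i,j) / (1 + |i - j|)`, and the mean and population standard
   deviation of unit-scaled intensities. Ten channels are analyzed: Gra,
   Red, Gre, Blu, Y, Cb, Cr (full-range BT.601), Hue, Sat, V (hexcone HSV).
6. **Features** (`extract_features()`): per channel and radius
   (`r = 5, 7, 10, 15`), the average and minimum over all regions of
   homogeneity, mean, and std — `10 x 4 x 6 = 240` features per image,
   named like `Blu-10-MM`. Dataset columns are normalized to `[-1, 1]`.
7. **Model** (`svm_rfe_rank()`, `channel_scores()`,
   `evaluate_classifier()`): SVM recursive feature elimination with a linear
   kernel ranks the features (one feature removed per iteration, smallest
   squared weight first, ties broken toward the earlier column); channel
   scores sum each channel's 24 ranks; classification is assessed by model
   accuracy, leave-one-out, and stratified seeded 10-fold cross-validation,
   reporting accuracy, precision, recall, F-measure, sensitivity and
   specificity. The source text prints precision with an FN denominator,
   identical to its recall — an evident typo; the standard TP/(TP+FP) is
   implemented.

## Numerical choices that matter

* **Quantization.** The worked co-occurrence example in the source uses raw
  small integers; real channels must be binned. The classical
  `graycomatrix` routine the source relies on self-scales its input to
  `[min, max]`. We apply that self-scaling at *image* level (default
  `quantize_range = NULL`): every region of one image shares a common gray
  scale, so regional contrast differences stay visible. Scaling each tiny
  region to its own min/max would make homogeneity scale-invariant and blind
  to exactly the contrast the method measures; a fixed `[0, 255]` range
  with `L = 8` leaves 32-unit bins that swallow the small dynamic range of
  the chroma channels (Cb/Cr homogeneity pins at 1). Both alternatives
  remain available through `glcm_spec()`.
* **Homogeneity normalization.** The printed homogeneity formula divides
  counts by `(M - dx)(N - dy)` and omits the `|i - j|` weighting, under
  which every properly normalized matrix scores a constant 1. The default
  is pair-count normalization with the standard inverse-difference weight;
  the literal forms are available (`denom_mode = "paper_dims"`,
  `mode = "paper_literal"`) and reproduce the printed `1/20` example under
  its stated `M = N = 5`.
* **Pairing mode.** The published pipeline multiplies the image by the 0/1
  region mask before computing the matrix, injecting background zeros into
  the counts. The default counts only pairs with both pixels inside the
  region, which is the faithful reading of "outside the boundary is noise";
  `pair_mode = "literal_product"` reproduces the published behavior.
* **Degenerate inputs.** Regions thinner than the offset produce a zero-pair
  matrix with a warning and are excluded from the homogeneity aggregates;
  empty circle-lesion intersections are skipped and counted; a lesion
  smaller than the contraction radius raises a classed error naming the
  problem.
* **SVM.** No SVM library exists in the supported R environment, so the
  package ships a small C-SVM: box-constrained dual coordinate descent on
  the kernel matrix with the bias absorbed as `K + 1`, which removes the
  equality constraint. Optimality is certified by the projected-gradient
  KKT residual (asserted in the tests). Linear, RBF and polynomial kernels
  are provided; RFE always uses the linear kernel, since weight-based
  elimination is only defined there. The evaluation default is C-SVM, RBF,
  `C = 1`, `gamma = 1/p` (the source tuned its SVM "after several
  experiments" without printing values). nu-SVM is not implemented.
  Normalization statistics are learned inside each training fold and applied
  to the held-out rows, avoiding leakage; whether the source normalized
  before or after splitting is unstated.
* **Elimination curves** use one fixed initial ranking (re-ranking inside
  each elimination step is the unstated alternative).

## The synthetic world

The clinical dataset behind the source study (100 images, 31 melanoma / 69
benign) is not deposited, so all quantitative claims are established on a
synthetic generator (`generate_lesion()`, `generate_dataset()`) that states
its world explicitly:

* Border: harmonic radial curve `r(theta) = R0 (1 + sum a_k cos(k theta +
  phi_k))`, base radius 22–30 % of the frame, two harmonics of amplitude
  0.02–0.08, center jittered up to 2 % — enough irregularity to exercise
  the centroid/scaling geometry non-trivially.
* Macro edge: logistic profile `skin + (lesion - skin) * sigmoid(-d / tau)`
  per RGB plane, with the edge width `tau` set per angular sector (8
  sectors, the virtual pie). Benign sectors draw `tau ~ U[6, 12]` px;
  malignant lesions set 1–3 sectors to `tau ~ U[0.5, 2]` px. A lesion is
  labeled malignant iff any sector has `tau <= 2` (a pure function of the
  spec, no randomness).
* Pigment pattern: a band-limited random field (Gaussian-smoothed white
  noise, correlation length 1.5 px, independent per plane, amplitude 40 % of
  each plane's skin-lesion contrast) whose local contrast is *depleted over
  a band of about `2 tau` inside the border*. This is the substantive
  modeling decision: for a pure monotone sigmoid edge, the
  inverse-difference homogeneity of a gradual ramp is never higher than that
  of an equal-rise step (a ramp has more level-changing pairs), so edge
  width alone cannot reproduce the clinical observation that abrupt borders
  depress peripheral homogeneity. What the B criterion describes is the
  pigment *pattern* terminating abruptly; modeling the pattern and its
  termination band makes abrupt sectors carry full-contrast texture right up
  to the border — where the shadow-border circles sample it — while gradual
  borders present an almost pattern-free rim. Setting
  `pattern_contrast = 0` recovers the literal sigmoid-only model (used in
  the tests that check the 50 %-threshold mask property).
* Noise: additive Gaussian, `sigma = 2` (8-bit units) — realistic sensor
  noise that stays below one quantization bin of the major channels.
* Colors: lesion (90, 60, 50) on skin (210, 170, 140), the darker-brown-on-
  tan convention of dermoscopy.
* The `tau_channels` option restricts the *class signal* to chosen RGB
  planes: non-responsive planes use a gradual macro edge and keep
  full-contrast pattern up to the border in every sample, acting as
  class-independent distractors. This is what makes the blue-injection
  probe identify the Blu channel itself rather than its scaled copies
  (Cb, Sat): under scale-invariant texture statistics and per-column
  normalization, a clean proportional copy of a channel is exactly as
  informative as the original.

What a green test on this world does establish: the geometry (tracing,
contraction, placement), the texture statistics against brute-force oracles,
the end-to-end discriminative behavior (LOO accuracy, channel recovery,
monotone response to the edge width). What it does not establish: clinical
performance. The generator has no hair, gel bubbles, rulers, asymmetric
pigment networks, or segmentation error, and the published real-data numbers
(96 % LOO accuracy, specificity 0.96, sensitivity 0.86, F 0.87) are not
reproducible without the original images.

Benchmark scales are chosen for desk runtime: the headline benchmark is
69 + 31 images at 256 x 256 (the source's class ratio at reduced
resolution); channel-recovery replicates use 40 images at 160 x 160 and the
edge-width monotonicity probe single lesions at 128 x 128.

## Known limitations

* Hue is treated as a linear scalar in the co-occurrence statistics; its
  circularity is not modeled (the source is silent on this).
* Image IO is plain-text PNM (P1/P2/P3) only — the supported R environment
  has no raster codec; binary PNG/JPEG/TIFF inputs must be converted
  externally.
* Chain-code direction labels follow a documented convention (0 = E,
  counter-clockwise increase); the source figure defining its grid is not
  machine-readable, and downstream computation depends only on the traced
  path.
* The method-2 failure mode is detected and reported, not repaired — the
  repair *is* method 3.
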