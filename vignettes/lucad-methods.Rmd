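---
title: "The lucad pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lucad pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lucad` implements a classical four-stage computer-aided detection (CAD)
pipeline for lung nodules on single 2D chest CT slices, together with a
synthetic chest phantom used to exercise every stage against known ground
truth. This vignette explains the science of each stage, the tunable
parameters and their defaults, the numerical choices, and what the phantom
does and does not demonstrate about real data.

## Pipeline overview

Stage I enhances the slice and extracts the lung fields; stage II detects
circular candidate structures inside the lungs and segments each candidate;
stage III summarizes every segmented nodule as a 123-element feature vector
and reduces it with PCA; stage IV classifies the reduced vector as benign
or malign with a probabilistic neural network (PNN), evaluated by
leave-one-out cross-validation (LOOCV).

All processing is strictly per slice. Intensities are min–max normalized
to [0, 1] when a slice is read (`readDicomSlice()`, `readImageSlice()`);
a constant slice maps to all zeros by convention. Physical pixel spacing
(mm) is carried on the `CTSlice` object because the detection radius bands
are specified in millimetres; when a file has no spacing attribute the
reader falls back to 0.7 mm — a 512-pixel chest field of view of roughly
36 cm — with a warning.

## Stage I: enhancement and lung volume extraction

Enhancement is the composition *median denoise → Laplacian sharpen →
histogram equalize* (`enhance()`). The order is a design choice: denoising
precedes differentiation so the Laplacian does not amplify single-pixel
noise, and equalization runs last so that the fixed thresholds of the lung
extraction see contrast-normalized input. Defaults: median window 3 px,
sharpening weight 0.5 with the 4-neighbour Laplacian
(`out = clip(in − 0.5·L(in))`, reflect padding), 256 equalization bins.
None of these values is critical; they are exposed in `enhanceConfig()`.

Lung volume extraction (`luvemExtract()`) marks pixels with enhanced
intensity strictly between a low and a high threshold (defaults 0.25 and
0.65) as candidate lung, removes every candidate component 4-connected to
the image border (background air and table artifacts), then applies binary
erosion (disk radius 2), dilation (disk radius 4) and interior hole
filling. Vessels and nodules inside the lung are brighter than the band
and fall out of the candidate set, but hole filling returns them to the
lung field, which is the desired behaviour for downstream detection. The
dual-threshold reading — candidate iff `low < value < high` — reflects the
intensity layout of an equalized chest slice: lung parenchyma sits in the
mid-dark band, soft tissue and bone above it, background air below or
border-connected. Erode-before-dilate removes the thin salt of background
pixels whose noise lands inside the band, at the cost of fine lung-margin
detail that the larger dilation radius restores.

An Otsu baseline (`otsuExtract()`) applies a single global threshold and
the same border clearing and morphology. On equalized images the global
histogram is nearly flat, so the Otsu threshold lands mid-scale and splits
the lung band itself; the dual-threshold method is markedly more robust on
the phantom, mirroring the gap the overlap metrics are designed to expose.
Segmentation quality is quantified by `jaccard()` and `dice()`
(`dice = 2J/(1+J)`; both are defined as 1 when the two masks are empty).

Empty extraction results are a warning, not an error, so that batch runs
survive degenerate slices.

## Stage II: candidate detection and nodule segmentation

Candidate detection (`chtDetect()`, `detectAllBands()`) is a gradient
circular Hough transform over three radius search bands in millimetres —
small 3–12, medium 10–20, large 15–45 — converted to integer pixel radii
by rounding outward so no band empties by truncation. The bands are taken
literally as radius ranges and are configurable, since the corresponding
size *categories* of the evaluation (<10, 10–20, >20 mm) are diameters.

The implementation is the classic two-stage variant with three
robustness choices, each motivated by a concrete failure mode observed on
phantoms during development:

* **Magnitude-weighted voting.** Every voting pixel votes along its Sobel
  gradient direction (toward brighter intensity, i.e. toward the centre of
  a bright nodule) at every radius of the band, with weight equal to its
  gradient magnitude normalized by the per-slice maximum. Unweighted
  voting was dominated by equalization-amplified pixel noise.
* **Interior-restricted voting.** A rim of about `2·sigma + 1` pixels is
  eroded off the lung mask before voting; the lung boundary itself is an
  arbitrarily strong intensity step whose arcs otherwise vote for spurious
  small circles inside the lung. A consequence worth knowing: nodules
  attached to the pleural wall (juxtapleural) lose part of their boundary
  evidence, a standard limitation of masked CAD detectors.
* **Scale-matched smoothing.** The slice is Gaussian-smoothed with
  `sigma = max(2, 0.2 × min band radius in px)` before gradients are
  taken. For large nodules this also rounds a spiculated margin so that
  its vote mass concentrates at the centre; with per-radius peak finding
  alone, spiculated boundaries spread their votes across radii and were
  missed.

Centre localization uses the accumulator summed over all radii of the band
(3×3 box-smoothed); each local maximum above the score gate then receives
the radius maximizing the circumference-normalized score
`votes / (2πr)`, and candidates below `scoreThreshold` (default 0.3, i.e.
30% of an ideal unit-weight circle's vote mass) are dropped. Greedy
nonmaximum suppression (`nonmaxSuppress()`) keeps a candidate only if its
centre is at least `max(5 px, smaller radius)` from every kept centre.
Detection is fully deterministic.

Each candidate is segmented by a per-ROI self-organizing map
(`somTrain()`, `somSegment()`). The ROI is a square of side
`2·ceil(1.5·r) + 1` (minimum 9 px) around the candidate; the SOM is a 1D
chain of 4 nodes (background, parenchyma texture, vessel/edge, nodule)
trained online for 20 epochs on the ROI's own pixels, feature vector =
(intensity, 3×3 mean), learning rate decaying exponentially 0.5 → 0.01 and
Gaussian neighbourhood 2 → 0.2 (the small final radius makes late updates
effectively winner-only, which the map needs to settle on well-separated
clusters). Training order and initialization are
drawn under a mandatory seed, making segmentation reproducible; the SOM is
the pipeline's only stochastic component. The nodule cluster is chosen by
cutting the intensity-ordered prototypes at their largest gap and taking
the bright group when it is tight (spread ≤ gap) — several nodes often
share the nodule intensity, and taking only the single brightest node
returned fragments; when the background forms an intensity continuum with
no gap, the rule falls back to the brightest cluster present under the
candidate circle. The mask is the largest 8-connected component at the
ROI centre, hole-filled, so it is always a single component or empty.

**Which image feeds which stage.** Lung extraction and detection consume
the fully enhanced slice — their thresholds assume contrast-normalized
input. Segmentation and feature extraction consume the *median-denoised*
slice instead. Histogram equalization maps each tissue's intensities onto
a range proportional to its area share, so a large nodule's internal noise
is stretched across much of the gray scale; on equalized input the SOM
fragmented large nodules (overlap dropping to zero on 40–60 mm cases) and
the intensity statistics no longer reflected acquisition noise. On the
denoised slice, phantom segmentation overlap (Dice) averages 0.97.

## Stage III: features and reduction

`extractFeatures()` produces the canonical 123-vector
(`featureNames()`): 6 first-order statistics (SSF), 16 shape descriptors
(SBF), 88 co-occurrence texture features (GTF, 22 descriptors × 4 angles),
and 13 wavelet energies (TEF). SSF are computed on the ROI pixels inside
the nodule mask; SBF on the mask; GTF and TEF on the masked bounding box
(the ROI multiplied by the mask, cropped to the mask extent and
zero-padded to the minimum input of each transform).

* **SSF**: mean, standard deviation, variance, skewness, kurtosis
  (population moments; zero-variance samples yield 0 by convention so
  vectors stay finite) and histogram entropy in bits over 256 bins.
* **SBF**: area, perimeter, circularity `4πA/P²`, eccentricity, solidity,
  extent, equivalent diameter, major/minor ellipse axes (second central
  moments with the 1/12 pixel-extent correction), aspect ratio, convex
  area and perimeter, convexity, compactness `P²/A`, and the mean and
  standard deviation of the boundary-to-centroid radial distance.
  Perimeter comes from the marching-squares contour smoothed with a
  5-point circular moving average: raw crack or chain-code lengths
  overestimate a digital disk's perimeter by 6–27%, biasing circularity
  to ~0.88, while the smoothed estimator is within about 0.5% of `2πr`.
  Spiculated masks score a larger radial spread and lower circularity
  than disks of equal area — the geometric signature of malignancy this
  stage is designed to capture.
* **GTF**: gray-level co-occurrence matrices at displacement 2 and angles
  0/45/90/135 degrees, 16 quantization levels, symmetrized and
  normalized; 22 descriptors per angle (the Haralick set plus common
  extensions: autocorrelation, contrast, correlation, cluster prominence
  and shade, dissimilarity, angular second moment, entropy, homogeneity,
  maximum probability, sum of squares, sum average/entropy/variance,
  difference variance/entropy, two information measures of correlation,
  inverse difference, two normalized inverse-difference variants, and the
  maximal correlation coefficient via the second eigenvalue of the
  transition form). Entropies are in bits; degenerate marginals yield 0
  rather than NaN.
* **TEF**: a 4-level 2D Daubechies-2 wavelet decomposition with symmetric
  extension; the 13 features are the relative energies of the 12 detail
  subbands plus the level-4 approximation, which are nonnegative and sum
  to 1. The transform was verified coefficient-for-coefficient against an
  independent reference implementation. Note that for any image with a
  nonzero mean the approximation retains the DC energy, so even a 1-px
  checkerboard keeps roughly half its energy there — its diagonal detail
  dominates the *detail* subbands.

Reduction is standardized PCA (`pcaFit()`): features mix px², bits and
ratios, so each column is centred and scaled (zero-variance columns pass
through). Components are ordered by explained variance and the sign of
each loading is fixed so its largest-magnitude entry is positive, making
fits fully deterministic. The retained count follows the class-size rule
(`nComponentsRule()`): at most one-third of the training patterns in the
smaller class, `floor(minClassSize × splitFraction / 3)` — with the
reference composition (smaller class 104, half split) this yields 17. In
LOOCV the PCA is refit on each training fold (no leakage); a
`pcaGlobal = TRUE` switch mimics a single global fit for comparison,
since a global fit is the other defensible reading of the protocol.

## Stage IV: classification and evaluation

The PNN (`pnnFit()`, `pnnPredict()`) stores every training vector as a
pattern unit and scores class `c` for query `x` as the mean of
`exp(−‖x−p‖²/(2σ²))` over class-`c` patterns — kernel *means*, equivalent
to uniform class priors, so the larger class cannot win on pattern count
alone (`priors = "proportional"` switches to frequency weighting, under
which the wide-kernel limit returns the class priors). Posteriors are
normalized scores; exact ties resolve to benign, favouring the non-cancer
call. Computation is in the log domain so near-delta kernels do not
underflow. The spread σ is selected per training fold by maximizing
leave-one-out accuracy over a 12-point log grid on [0.05, 5], ties to the
smaller σ — a deterministic rule, recorded per fold in the run log.

Evaluation (`confusion()`, `performanceMetrics()`, `rocAuc()`, `loocv()`,
`sizeStratifiedReport()`) treats malign as the positive class and reports
accuracy, sensitivity, specificity, positive and negative decision value
(the precision of the positive and negative call) as percentages, and F1
as a fraction. Display rounding is half-up to two decimals; full precision
is kept internally, and metrics with a zero denominator are reported as
`NA`, never as 0 or 100. ROC/AUC uses a threshold sweep with trapezoid
integration, which equals the normalized Mann–Whitney U statistic with
ties counted half. Size-stratified reports partition diameters into
[0, 10), [10, 20] and (20, ∞) mm; the band confusion matrices always sum
to the overall matrix.

## The synthetic phantom

`phantomSlice()` renders a 512×512 slice at 0.7 mm spacing: a dark
background (0.03), a bright body ellipse (0.75), two dark lung ellipses
(0.15), 5–15 bright vessel segments (0.6), an optional mid-intensity
table arc touching the lower border (0.45; exercises border clearing),
planted nodules (0.55) and additive Gaussian noise (sd 0.02), clipped to
[0, 1]. Benign nodules are disks with a Gaussian-blurred margin (sd
1.2 px) and low internal noise (sd 0.01); malign nodules have a
star-convex boundary `r(θ) = r₀(1 + A·max(s(θ), 0))` — outward spicules
from a round core, with `s` a normalized harmonic series of order 8–12
and `A = 0.3` — and higher internal noise (sd 0.05). Malignancy is thus
encoded exactly as the two cues the classification stage is built to
read: boundary irregularity and texture variance. Spicules extend
*outward only* because spiculation is a star-like extension of a compact
core; a symmetric ±A perturbation would (and in an early version did)
move the dominant circular response to the valley radius `0.7·r₀`,
outside the nominal radius band — a generator artifact, not a property of
nodules.

Geometry is chosen so that, after equalization, the cumulative
distribution places lung-field intensities inside the (0.25, 0.65)
extraction band — the analogue of the intensity layout of real chest CT
that motivates those thresholds. Nodules are placed before vessels and
vessels keep a 3-px clearance from every planted nodule: a vessel fused
to a nodule would silently change the shape that the label describes.
Nodules never overlap (placement retries, then errors with advice), and
every nodule mask is a subset of the lung truth.

`phantomDataset()` samples diameters per size band (defaults mirror the
reference composition: 104 benign + 116 malign over bands 75/65/80),
packs nodules onto slices (at most 3 per slice, fewer for large ones) and
emits a manifest plus optional PNG artifacts. Everything is deterministic
given the seed.

**What the phantom does not show.** It has no Hounsfield calibration, no
3D partial-volume structure, no juxtapleural or juxtavascular nodules, no
ground-glass opacities, and its benign/malign contrast is by construction
aligned with the feature set. Passing the phantom study therefore
demonstrates that the pipeline is internally consistent and recovers a
planted signal of the stated kind — not that it reaches any particular
accuracy on clinical data.

## Problem sizes used in the test suite

The packaged checks run the lung-extraction study on 20 phantom slices,
detection accuracy on 50 planted disks, segmentation overlap on 20 disk
ROIs, and the end-to-end LOOCV study on a 60-nodule phantom dataset
(30 benign / 30 malign over 20 size-balanced slices, the class-size rule
giving 4 components per fold). On that study the pipeline reaches
accuracy well above the 80% gate (93% at the development seed) with AUC
about 0.96 and detection recall about 0.93; the numbers are recomputed,
not asserted, on every run.

## Known limitations

* Strictly 2D: no slice stacking, no volumetric features.
* The radius-band reading (radii, not diameters) is configurable but
  unresolved in principle; at 0.7 mm spacing the smallest nodules
  (3–6 mm diameter) fall below the smallest band and are only reachable
  through the annotation-fallback path of `runPipeline()`.
* Juxtapleural nodules lose boundary evidence to the mask-interior
  voting restriction.
* The DICOM reader supports uncompressed single-frame little-endian
  files only — sufficient for fixtures and typical exports, not a
  general DICOM implementation.
* The 16 shape and 22 texture descriptor identities are a package
  convention (their counts, distances and angles are fixed by the
  method); other implementations may choose different supersets of the
  Haralick set.
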