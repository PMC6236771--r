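# lucad — lung-nodule computer-aided detection on CT slices

`lucad` implements a classical four-stage computer-aided detection (CAD)
pipeline that takes a 2D chest-CT slice and ends with a benign/malign call
for every detected pulmonary nodule. It is aimed at researchers who want a
fully inspectable, deterministic reference implementation of the
pre-deep-learning CAD stack — every stage is a documented R function with
its own unit and oracle tests — and at teaching settings where each stage
(enhancement, lung extraction, candidate detection, segmentation, feature
extraction, dimensionality reduction, classification) can be run and
examined in isolation.

All randomness in the package is scoped to explicit seeds, so every result
in this README is exactly reproducible.

## The pipeline

**I. Enhancement** (`enhance()`): 3×3 median denoising, Laplacian
sharpening `g = f − w·∇²f` (4-neighbour kernel, reflect padding), and
histogram equalization via the binned empirical CDF.

**II. Lung extraction** (`luvemExtract()`): lung-field candidates are the
pixels whose equalized intensity lies in an open band `(low, high)` —
default `(0.25, 0.65)` — followed by removal of border-connected
components (scanner table, background air), morphological opening-style
cleanup (erosion r=2, dilation r=4, disk elements) and hole filling. An
Otsu-threshold baseline (`otsuExtract()`) is provided for comparison, and
`jaccard()` / `dice()` score either against a reference mask:

    J(A,B) = |A ∩ B| / |A ∪ B|,   D(A,B) = 2|A ∩ B| / (|A| + |B|).

**III. Candidate detection and segmentation**: a gradient circular Hough
transform (`chtDetect()`, `detectAllBands()`) votes along Sobel gradient
directions over three radius bands (small 3–12 mm, medium 10–20 mm, large
15–45 mm, radii in mm converted by the slice's pixel spacing); centres come
from a radius-summed accumulator, radii from a per-centre score profile
normalized by circumference. Each surviving candidate is segmented by a
per-ROI self-organizing map (`somTrain()`, `somSegment()`): a 1D chain of
4 prototypes trained online on (intensity, 3×3 mean) pixel features,
learning rate 0.5 → 0.01, Gaussian neighbourhood 2 → 0.2, 20 epochs; the
nodule is the largest connected component of the bright prototype group at
the candidate centre, holes filled.

**IV. Features, reduction, classification** (`extractFeatures()`,
`pcaFit()`, `pnnFit()`): each segmented nodule yields a 123-value vector —
6 statistical (mean, s.d., variance, skewness, kurtosis, entropy),
16 shape/boundary (area, perimeter, circularity, convexity, radial
statistics, moments, …), 88 gray-level co-occurrence texture features
(22 Haralick-style descriptors × 4 angles, d = 2, 16 levels) and
13 wavelet energies (4-level db2 DWT, relative subband energies summing
to 1). PCA reduces the standardized features to

    k = max(1, ⌊ n_min · s / 3 ⌋)

components, where `n_min` is the smaller class size and `s` the training
split fraction (`nComponentsRule(104, 0.5) = 17`). Classification is a
probabilistic neural network — per-class Parzen kernel means

    score_c(x) = (1/n_c) Σ_{p ∈ c} exp(−‖x − p‖² / 2σ²)

computed in the log domain, σ selected by leave-one-out accuracy on a log
grid. `loocv()` and `sizeStratifiedReport()` produce the standard
confusion-matrix criteria (Acc/Sen/Spc/PDV/NDV/F1), ROC AUC (equal to the
Mann–Whitney U statistic, ties counted half) and per-size-band tables.

Because no public CT data ships with the package, `phantomSlice()` /
`phantomDataset()` generate seeded synthetic chest phantoms with exact
ground truth: dark lung fields inside a bright body ellipse, vessels, a
table artifact, and planted nodules — benign ones round and smooth, malign
ones spiculated (star-convex outward spicules) with higher internal
texture variance.

## Worked example

A 60-nodule study (30 benign / 30 malign, 20 nodules per diameter band),
fully seeded:

```r
library(lucad)
ds  <- phantomDataset(nBenign = 30L, nMalign = 30L,
                      sizeBins = c(20L, 20L, 20L), seed = 42)
run <- runPipeline(ds, pipelineConfig(seed = 7))
run$loocv$report
#> TP=29 FP=1 FN=1 TN=29 | Acc 96.67  Sen 96.67  Spc 96.67
#>                         PDV 96.67  NDV 96.67  F1 0.97
run$loocv$auc
#> [1] 0.9822222
sum(run$detection$detected)          # CHT found 56 of the 60 nodules
#> [1] 56
run$loocv$sizeReport[, c("band", "n", "Acc", "Sen", "Spc")]
#>      band  n    Acc    Sen    Spc
#> 1     <10 20  90.00  90.91  88.89
#> 2   10-20 20 100.00 100.00 100.00
#> 3     >20 20 100.00 100.00 100.00
#> 4 overall 60  96.67  96.67  96.67
```

Every fold of the leave-one-out loop refits PCA (here the class-size rule
gives 4 components) and reselects σ, so the reported accuracy contains no
train/test leakage. The same pipeline is scriptable from the shell via
`inst/cli/lucad.R` (`phantom`, `lungseg`, `detect`, `run`, `report`
subcommands).

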