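---
title: "Methods: shape-mode morpho-phenotyping with morphomodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-mode morpho-phenotyping with morphomodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphomodes)
```

## The analysis problem

Cell populations -- cancer cell lines in particular -- are morphologically
heterogeneous: cells drawn from one line display a wide range of cell and
nuclear shapes that single-number descriptors (area, shape factor, aspect
ratio) do not capture. `morphomodes` quantifies that heterogeneity directly
from boundary outlines. The pipeline has four core steps:

1. **Registration.** Each closed outline (cell or nucleus) is resampled at
   50 points equally spaced in arc length and normalized for position,
   size and orientation. Size is recorded as the scaling factor *R*, the
   root-mean-square distance of the 50 boundary points from their centroid
   (centroid size), reported separately for nuclei (*R~N~*) and cells
   (*R~C~*).
2. **Eigenshapes.** The registered outlines, written as 100-vectors
   (50 x-coordinates then 50 y-coordinates), are decomposed by
   mean-centered covariance PCA. The smallest number of components whose
   cumulative explained variance reaches 95% (configurable) forms the
   eigenshape basis; every shape is summarized by its projection scores.
3. **Shape modes.** K-means clustering of the scores identifies recurrent
   morphologies ("shape modes"). The number of modes is chosen by
   minimizing the Xie-Beni validity index over a candidate range; a
   Dunn-style separation index is reported alongside as a diagnostic.
   Mode centroids are mapped back through the eigenshape basis to draw a
   gallery of representative outlines.
4. **Heterogeneity profile.** Each sample is summarized by five metrics:
   CV(*R~N~*), CV(*R~C~*) (coefficients of variation of nucleus and cell
   size) and the Shannon entropies *S*(NS), *S*(CS), *S*(NS&CS) of the
   nucleus-mode, cell-mode and paired-mode distributions, in bits.

Context modules attach per-cell covariates: cell-cycle phase gated from
integrated nuclear DNA intensity, and local cell density
$\rho_D$ (the number of touching neighbors from a label-mask contact
graph). The heritability module quantifies where size variance comes from
(cell cycle, cell contact, stochastic, heritable/clonal) and classifies
samples from a three-feature heterogeneity signature.

## Registration: conventions and numerical design

A registered shape satisfies, on its 50 points exactly: centroid at the
origin, RMS radius 1, second-moment cross term 0 with x-variance at least
y-variance (major axis horizontal), counterclockwise orientation (positive
shoelace area), and the starting index at the point of largest x (ties:
largest y). The 180-degree ambiguity of the major axis is resolved by
requiring the third moment of x to be nonnegative; mirror images are kept
distinct, since nothing in the analysis motivates pooling a shape with its
reflection.

Two numerical choices deserve explanation:

* **Index-free provisional frame.** The centroid, size, principal axis and
  skew sign used to set up registration are computed as exact arc-length
  line integrals over the polygon (closed-form per edge), not from the
  vertex list. Consequently registration is invariant, to floating-point
  precision, under translation, rotation, uniform scaling *and cyclic
  re-indexing* of the input vertices -- the properties the test suite
  checks at 1e-6.
* **Fixed-point resampling.** Equal-arc-length resampling of a polygon
  whose vertices are not equally spaced does not return its own vertices,
  so a single-pass resample is not idempotent. Registration therefore
  iterates the resample until the 50 edges have equal length (tolerance
  1e-12 relative, at most 400 iterations; convergence is geometric and
  typically takes a few dozen iterations). Re-registering a registered
  shape then reproduces it to better than 1e-9. The iteration moves
  points by at most the chord-sagitta distance of the 50-gon -- the same
  order as the discretization error already accepted by using 50 points.
  The standalone `resample_boundary()` remains a single-pass operation
  with first point at the trace's first vertex, and matches a brute-force
  cumulative-arc-length oracle at 1e-9.

Degenerate inputs: zero-perimeter or coincident-point traces raise a
degenerate-shape error; circular-symmetric shapes (equal second-moment
eigenvalues) take rotation 0 and are flagged.

## Eigenshapes and shape modes

PCA is covariance-based (no per-feature standardization): after size
normalization all 100 coordinates share the same dimensionless units, so
correlation scaling would only inflate low-variance coordinates. One model
is fitted per compartment on the pooled multi-sample data, so that mode
catalogues and entropies are comparable across samples. Component signs
are fixed (largest-magnitude entry positive) for reproducible score signs.

The Xie-Beni index for a hard clustering is
$XB = \sum_i \lVert x_i - c_{l(i)}\rVert^2 / (n \min_{j\neq k}\lVert c_j -
c_k\rVert^2)$; lower is better, and the selected K minimizes it. The
"separation index" in the literature is not uniquely defined; we implement
the Dunn-style ratio of minimum between-centroid distance to maximum
cluster diameter and report it as a diagnostic only, because Xie-Beni has
an unambiguous formula and no arbitration rule between the two indices is
available. Zero-diameter (point-mass) clusters cap the separation at the
sentinel 1e12 to keep diagnostics finite. K-means uses restarts from
distinct data rows (default 20) keeping the lowest inertia, with a
recorded seed; mode ids are ordered by descending cluster size so
galleries are stable. A `low_confidence` flag is raised when the Xie-Beni
minimum is not a strict interior local minimum over the scanned range --
the situation for data without cluster structure, where the selected K is
not meaningful.

## Heterogeneity metrics

Entropies use log base 2 (bits); the base only rescales comparisons.
Probabilities are computed against the *global* mode catalogue with
zero-count modes contributing zero, so panels are comparable across
samples and conditions. The CV uses the sample (n-1) standard deviation;
at the per-sample cell counts this package targets (hundreds to
thousands) the n vs n-1 choice is immaterial, but it is fixed and
documented, and the tests assert the exact sd/mean identity. The plug-in
entropy estimator is used without small-sample bias correction
(Miller-Madow and relatives are a possible extension); conditioned panels
with fewer than 2 cells are marked unavailable rather than estimated.

## Cell-cycle gating and local density

Integrated nuclear DNA intensity is normalized by the G0/G1 peak, located
as the dominant mode of a kernel density estimate of the raw intensities;
this makes gating invariant to detector gain. Gates default to G0/G1
below 1.25 and G2/M above 1.75 fold-of-G1 -- conventional image-cytometry
positions, exposed in the configuration because the boundary between S
and the flanking phases is not observable from DNA content alone. A
threshold gate cannot, even in principle, recover the true phase of
S-phase cells whose DNA content lies inside the flanking gates; accuracy
is therefore assessed against the phase the gates imply for the
noise-free content, which isolates what the gating controls (peak
normalization and noise robustness). Samples with fewer than 50 cells are
flagged low-confidence.

Contact: two cells touch when their label masks come within
`contact_gap` (default 1) pixels, implemented as a shift-overlap test
equivalent to dilation by a square brush. Density categories follow
$\rho_D = 0$ (singlet), $0 < \rho_D < 4$ (semi-crowded), $\rho_D \ge 4$
(crowded). Tiled acquisitions are composed into one global canvas by
their stage origins before the contact test, so contacts straddling tile
borders are preserved; tiles that disagree about a label at an
overlapping pixel raise a conflict error.

## Heritability analyses

Colonies (clones grown from sparse seeding) are recovered by
single-linkage clustering of cell positions with a distance cutoff;
colonies under 5 cells are left unassigned. Variance decomposition
reports the population variance of *R~N~* and *R~C~* within condition
subsets, scaled by the all-population variance (the "all" entry is 1
exactly); the within-clone entry is the mean of within-colony variances.
Proximity correlation computes the Pearson correlation of a feature over
cell pairs in distance bins, entering each unordered pair in both orders
so the estimator is exchangeable, and compares it to a 2.5/97.5%
permutation band (default 1000 permutations, seeded). Note two small-n
facts the tests respect: between-colony pairs carry an O(1/#colonies)
negative bias when a real colony effect exists, and the probability that
*all* bins sit inside a 95% band simultaneously is below 0.9 for 3+ bins,
so coverage is assessed per bin.

The metastasis-signature features are CV(*R~N~*) among clustered cells
($\rho_D > 0$), CV(*R~C~*) among singlets, and *S*(NS) among singlets.
Classification is leave-one-sample-out nearest-centroid on z-scored
features -- deliberately the simplest possible classifier, so that
discriminative power is attributable to the features, not the model.
Subsampling cross-validation redraws the stated number of cells per
sample and recomputes the features per repeat.

## The synthetic-scene generator

Ground truth for every stage comes from the generator, not from deposited
data. Templates are star-convex radial Fourier outlines
$r(\theta) = 1 + \sum_{h=2}^{6} a_h\cos h\theta + b_h\sin h\theta$ with
harmonic amplitudes scaled by an `irregularity` parameter and clamped so
the radius stays positive -- simple, guaranteed-simple closed curves that
produce visually distinct morphologies. When `min_separation` is set,
candidate templates are redrawn until their registered feature vectors
are at least that far apart and their x-skewness magnitude exceeds 0.05;
latent subtypes are distinct morphologies by definition, and the skewness
floor prevents the 180-degree orientation convention from splitting a
template's noisy instances into two apparent modes.

Per cell, DNA content is drawn as G0/G1 = 1.0, G2/M = 2.0, S uniform in
(1, 2) with default weights 0.60/0.15/0.25, and cell and nucleus scale
multiply by the cube root of DNA content (size grows with genome
content). Default noise settings -- shape noise 0.05 on the harmonic
coefficients, 5% lognormal size and intensity noise, read noise at SNR
20 -- are stated in the configuration as plausible imaging conditions;
no claim is made that they match any particular instrument. Rendered
scenes make integrated nuclear intensity exactly proportional to DNA
content before noise, which is what makes the gating round-trip testable.
The generator does **not** emulate uneven illumination, point-spread
blurring, focus drift, debris, or segmentation-adversarial textures, so
green tests certify the pipeline's statistical machinery on clean
geometry, not robustness to every real-microscope artifact.

Standard problem sizes used by the test and acceptance suites -- 2000
cells for mode recovery over 20 seeds, 1000-cell two-sample scenes for
the entropy-ordering property, 5000 cells for variance-component
recovery -- were chosen as the smallest populations at which the
corresponding statistics are stable.

## Segmentation stand-in

The imaging front end segments nuclei from the smoothed,
background-subtracted DNA channel (Otsu threshold, hole filling,
distance-transform watershed to split touching nuclei; tolerance 2 chosen
because tolerance 1 over-split lobed synthetic nuclei) and cells by
seeded region growing (`EBImage::propagate`) on the actin channel
restricted to its Otsu foreground. This is a stated, configuration-
isolated design -- any external segmenter can be substituted by supplying
label masks via `labeled_scene()`. Boundaries are traced at the 0.5
iso-level of each label's binary mask, so polygon areas match pixel
counts to within a boundary-pixel band. 3D samples are handled by
Gaussian low-pass filtering each z-slice and taking the per-pixel maximum
projection before the 2D pipeline.

## Known limitations

* Star-convex templates cannot express strongly concave or branched
  morphologies; the registration itself handles any simple closed curve.
* Threshold DNA gating leaves S-phase boundaries intrinsically uncertain
  (see above).
* The plug-in entropy estimator is biased downward for very small
  per-condition cell counts.
* The classifier is intentionally minimal; with many samples per class a
  cross-validated discriminant analysis would be natural.
* The pipeline's simulated study uses a sample-specific skew over shared
  templates to create heterogeneity differences between samples; real
  samples differ in more ways than mode weights.
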