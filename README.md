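# morphomodes

Shape-mode morpho-phenotyping of cell populations from fluorescence
microscopy.

Cancer cell lines — and cell populations generally — are morphologically
heterogeneous in ways that single-number descriptors (spreading area,
shape factor, aspect ratio) cannot express. `morphomodes` quantifies that
heterogeneity directly from cell and nucleus boundary outlines, for
researchers doing high-content imaging of cultured cells who want
per-sample heterogeneity profiles, cell-cycle/density-resolved
morphology, and clonal (heritable) variance estimates at single-cell
resolution.

## The method

For each segmented cell and nucleus outline:

1. **Registration** — the closed boundary is resampled at 50 points
   equally spaced in arc length and normalized for translation, scale and
   rotation (major axis horizontal). Size is kept separately as the
   scaling factor *R* = RMS distance of the boundary points from their
   centroid (*R<sub>N</sub>* nucleus, *R<sub>C</sub>* cell).
2. **Eigenshapes** — mean-centered PCA of the registered 100-vectors;
   the smallest basis capturing 95% of shape variance represents every
   shape by its projection scores.
3. **Shape modes** — K-means clustering of the scores finds recurrent
   morphologies; K is selected by minimizing the Xie–Beni index
   XB = Σᵢ‖xᵢ − c<sub>l(i)</sub>‖² / (n·min<sub>j≠k</sub>‖c<sub>j</sub> −
   c<sub>k</sub>‖²), with a Dunn-style separation index reported as a
   diagnostic.
4. **Heterogeneity panel** — per sample: CV(*R<sub>N</sub>*),
   CV(*R<sub>C</sub>*), and Shannon entropies *S*(NS), *S*(CS),
   *S*(NS&CS) of the nucleus-, cell- and paired-mode distributions
   (bits).

Context modules gate cell-cycle phase from integrated nuclear DNA
intensity (G0/G1 peak normalization), build cell–cell contact graphs from
label masks (local density ρ_D; singlet / semi-crowded / crowded), and
decompose size variance into cell-cycle, contact, stochastic and
heritable (between-colony) components, including a three-feature
heterogeneity signature with subsampling cross-validated classification.
A synthetic-scene generator (latent shape templates, DNA-coupled sizes,
colonies, contact layouts, two-channel rendering) provides ground truth
for every stage.

## Worked example

```r
library(morphomodes)

## simulated two-sample study: S01 draws templates uniformly,
## S02 is skewed toward two dominant morphologies
res <- run_pipeline(list(seed = 5, n_samples = 2, cells_per_sample = 60,
                         templates_k = 3, k_max = 5, n_init = 4,
                         sample_skews = c(0, 1.5)),
                    out_dir = "run1")
#> [pipeline] simulate: 2 samples x 60 cells
#> [pipeline] register: 240 traces
#> [pipeline] nucleus: m = 5 eigenshapes, K = 3 modes
#> [pipeline] cell: m = 5 eigenshapes, K = 5 modes
#> [pipeline] context: gating + contacts
#> [pipeline] profile: mode distributions + heterogeneity panels
#> [pipeline] heritability: variance decomposition
#> [pipeline] done: 120 cells, outputs in run1

subset(res$panels, condition_tag == "all",
       c(sample_id, cv_nucleus_size, entropy_nucleus, entropy_joint))
#>   sample_id cv_nucleus_size entropy_nucleus entropy_joint
#> 1       S01       0.1551631        1.467901      2.486971
#> 8       S02       0.1120229        1.328515      2.417274
```

The uniform-weight sample (S01) scores the higher nucleus-shape entropy
(1.47 vs 1.33 bits) and the higher paired-mode entropy — the pipeline's
heterogeneity readout — while the size CVs, which are driven by the
shared cell-cycle and size-noise settings, differ less. `run1/` holds the
registered-shape table, eigenshape models, mode diagnostics and
centroids, per-cell records, heterogeneity panels, trend tables,
variance decomposition, signature features, and a `manifest.json` with
seeds and output hashes (identical configs reproduce identical files).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/morphomodes-cli.R run-all --config run.cfg --out out/
```

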