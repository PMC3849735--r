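# histohet

Spatial heterogeneity of tumor proliferation from stained virtual
slides, and its prognostic value for disease-free survival.

## What it does

Pathologists have long counted mitoses; this package also asks *where*
they are. Two tumors with the same mitotic index may distribute their
proliferating cells uniformly or concentrate them in hot spots, and
that spatial organization can carry prognostic information of its own.
`histohet` implements the full analysis chain:

- **Imaging** — read a stained slide (PNG/TIFF) at its native
  resolution (e.g. 0.5 µm/px), decimate it by Daubechies-2 wavelets to
  a 4 µm/px working image (÷8), detect immunopositive (mitotic) nuclei
  by DAB color deconvolution + Otsu thresholding + connected
  components, and compute the mitotic index per 1.7 mm².
- **Spatial statistics** — Voronoï pavements ("zones of influence") of
  the detected nuclei clipped to the region of interest, with the
  normalized variance of pavement areas; hot-spot detection from
  adjacent small pavements; quadrat counts with Fisher's index of
  dispersion (variance/mean, ≈1 under complete spatial randomness) and
  the normalized variance of density.
- **Texture** — gray-level co-occurrence (Haralick) energy and
  correlation on the working image, where one pixel ≈ one cell.
- **Composite scores** — standardization, greedy correlation pruning
  to a nonredundant feature subset, and PCA of the correlation matrix
  giving composite heterogeneity scores **CP1–CP3** (signs oriented so
  higher = more heterogeneous).
- **Prognosis** — Kaplan–Meier estimation, log-rank screening,
  multivariate Cox regression (Efron ties), and a three-poor-factor
  risk model: mitotic index > 10 (strict), axillary node involvement,
  upper tercile of CP2, grouped as 0 / 1–2 / 3 factors.
- **Synthetic ground truth** — generators for CSR and Thomas-process
  clustered slides, per-patient feature tables with planted latent
  structure, and survival cohorts with known hazard ratios, so every
  stage is testable without clinical data.

In the core model, the hazard of an oncological event for patient $i$
is $\lambda_i(t) = \lambda_0(t)\,\exp(\beta_1 \mathrm{CP2}_i +
\beta_2 [\mathrm{MI}_i > 10] + \beta_3 N_i)$, and the reported relative
risks are $e^{\hat\beta}$ from the Cox partial likelihood.

## Worked example

Render a clustered synthetic slide, extract its features, then analyze
a synthetic 368-patient cohort:

```r
library(histohet)
reg   <- region(1000, 1000)                       # 1 mm^2, um units
pat   <- generate_clustered_pattern(cluster_spec(15, 10, 35), reg, seed = 2)
slide <- render_slide(pat, resolution = 1, nucleus_radius = 3, seed = 3)
cfg   <- pipeline_config(native_resolution = 1, decimation_levels = 2)
run_slide(cfg, slide, slide_id = "demo")
#> n_nuclei 118, mitotic_index 200.6 per 1.7 mm^2,
#> voronoi_variance 1.937, fisher_index 8.537, norm_density_variance 1.809,
#> haralick_energy 0.960, haralick_correlation 0.203, ...
```

A Fisher index of 8.5 (vs ≈1 for a homogeneous pattern) and a
normalized Voronoï variance of 1.9 say the mitoses are strongly
clustered; the mitotic index alone would not reveal that.

```r
d   <- make_demo(tempdir(), seed = 7, n_slides = 2, n_patients = 368, cfg = cfg)
res <- run_cohort(cfg, d$features_csv, d$cohort_csv, out_dir = "results")
res$cox
#>           term   beta    hr     se     z        p
#> 1          CP2 0.3010 1.351 0.0698 4.309 1.64e-05
#> 2 mitotic_high 0.6104 1.841 0.1587 3.847 1.20e-04
#> 3     node_pos 0.9849 2.677 0.1622 6.071 1.27e-09
res$risk_logrank   # chi-square 63.4, p = 1.7e-14 across the 3 risk groups
table(res$risk_groups$group)
#>       0 factor 1 or 2 factors      3 factors
#>             87            259             22
```

The cohort was simulated with true hazard ratios 1.46 (CP2), 1.71
(mitotic index > 10) and 2.20 (node status); the fitted values above
are one 368-patient draw. The three risk groups separate sharply in
disease-free survival.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/histohet.R", package="histohet"))')" \
    demo --out demo/ --seed 7
```

with `slide --image X.png --roi X_roi.csv --out features.csv` and
`cohort --features features.csv --cohort cohort.csv --out results/`
subcommands.

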