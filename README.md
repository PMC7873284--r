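# srp3d

3D texture description of cell nuclei for phenotype classification and
chromatin condensation measurement.

## What it does

Changes in nuclear phenotype (cell-cycle arrest, epithelial–mesenchymal
transition, oncogenic transformation) begin as chromatin remodelling:
heterochromatin (HC, condensed, bright under DAPI) coarsens or opens into
euchromatin (EC, diffuse, dim). `srp3d` quantifies that remodelling in 3D
fluorescence stacks for image analysts and mechanobiologists who need
interpretable, non-deep-learning texture features:

* **3D SRP descriptor.** Each volume is tiled into 5×5×z cubic patches.
  Inside a patch, sampling hyperplanes are built between every (bottom
  column, top column) pair and rasterized with a 3D Bresenham line; every
  plane yields five sorted patterns — global, square-ring, circular-ring
  intensities and angular/radial differences — compressed by fixed ±1
  random-projection matrices, *f*ₓ = RPₓ · *x*ˣ with output dimension
  *a* = 10(*n*−1). Pooled per plane family (YZ, XZ, XY) into 16-bin
  histograms: 80 values per family, 240 per patch. A pseudo-3D variant
  (slice-wise, 80 values) quantifies what the third plane adds.
* **Image encoding.** Bag-of-visual-words (seeded k-means codebook, hard
  assignment, sum pooling, elbow-selected k over {32, 64, 96, 128, 160})
  or Fisher vectors (diagonal GMM, dimension 2·G·D).
* **Classification.** RBF-kernel SVM (C = 1, median-heuristic gamma on
  100 sampled training rows) under grouped 10-fold cross-validation —
  all cells of one 3D image stay in one fold, codebooks/scalers/gamma are
  fit per training fold — reporting AUC, F1, precision, recall; plus
  Kruskal–Wallis model comparison and a one-sided t-test for 3D versus
  pseudo-3D.
* **HC/EC metrics.** Per nucleus, the intensity ratio (from pooled f_G)
  and the aggregation ratio (from pooled f_R, f_A):
  HC/EC = Σ[f]_HC / (Σ[f]_Nucleus − Σ[f]_HC), thresholded at the minimum
  non-zero per-patch maximum; groups compared by a two-sided Wilcoxon
  rank-sum test at 1%.
* **Synthetic phantoms.** A DAPI-like nucleus generator (ellipsoid, smooth
  euchromatin texture, feathered bright foci) with condensed/open presets,
  so the whole pipeline is testable without external data.
* **I/O + CLI.** Multi-page grayscale TIFF in/out, nucleus cropping from
  label masks, and subcommands `simulate`, `features`, `encode`,
  `chromatin`, `classify`.

## Worked example

Generate 12 condensed and 12 open phantom nuclei, measure HC/EC, compare
the groups, and cross-validate a classifier:

```r
library(srp3d)

bank <- make_rp_bank(2, seed = 42)        # one +/-1 projection bank per analysis
co   <- make_cohorts(12, seed = 7)        # condensed vs open presets

ratios <- t(vapply(co$volumes, function(ph) {
  d <- describe_volume(ph$volume, bank)   # 432 patches x 240 dims per volume
  c(intensity   = as.numeric(hc_ec_intensity(d)),
    aggregation = as.numeric(hc_ec_aggregation(d)))
}, numeric(2)))
cond <- co$labels == "condensed"
round(colMeans(ratios[cond, ]), 2)
#>   intensity aggregation
#>        7.36       48.00
round(colMeans(ratios[!cond, ]), 2)
#>   intensity aggregation
#>        5.62       35.08
compare_groups(ratios[cond, "intensity"], ratios[!cond, "intensity"])
#> Wilcoxon rank-sum: z = 4.1569, p = 3.23e-05 (alpha = 0.01) -> reject H0; shift: group A > group B

sets <- lapply(co$volumes, function(ph) describe_volume(ph$volume, bank))
rep  <- run_cv(sets, co$labels, paste0("vol", 1:24), seed = 2026, k = 10,
               encode = list(method = "bovw", k = 32), pos_label = "condensed")
rep$mean[c("auc", "f1")]
#> auc  f1
#>   1   1
```

Condensed phantoms carry more of their projected signal mass above the HC
threshold (higher ratios), the intensity shift is significant at the 1%
level with the condensed group on top, and the 3D SRP + BOVW + SVM
pipeline separates the cohorts perfectly under grouped 10-fold CV. (At
n = 12 per class the aggregation ratio's rank-sum p is 0.028; at the
acceptance scale of n = 30 per class both ratios reject at 1%.)

The same pipeline from the shell:

```sh
srp3d simulate --n 12 --seed 7 --out cohort/
srp3d features --input cohort/ --out feats/ --mode 3d --seed 42
srp3d chromatin --input cohort/ --labels cohort/labels.csv --out chrom
srp3d encode --input feats/ --k 32 --out encoded.csv
```

(`srp3d` is the wrapper installed at `inst/cli/srp3d`; equivalently call
`srp3d_cli(c("simulate", ...))` from R.)

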