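---
title: "3D sorted random projections for nuclear chromatin texture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D sorted random projections for nuclear chromatin texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromatin remodelling — heterochromatin (HC) condensing out of euchromatin
(EC) or opening back up — changes the fine-grained texture of a
DAPI-stained nucleus before gross shape changes become visible. `srp3d`
quantifies that texture in 3D confocal stacks for two purposes: (i)
classifying nuclear phenotypes from texture alone, and (ii) measuring how
much of the nuclear signal sits in bright condensed aggregates (HC/EC
ratios). The descriptor at its core is a volumetric extension of sorted
random projections (SRP), a rotation-invariant patch descriptor built from
sorted intensity and difference patterns compressed by fixed ±1 random
matrices.

## The descriptor

### Patterns of a square patch

A $(2n+1)\times(2n+1)$ patch (default $n=2$, $5\times5$) is summarized by
five pattern vectors:

* $x^{Glob}$ — all pixels, sorted;
* $x^{Sqr}$ — the centre pixel, then each concentric square (Chebyshev)
  ring sorted, innermost first; ring $i$ holds $8i$ pixels;
* $x^{Circ}$ — the centre, then bilinear samples on concentric circles,
  sorted per ring; ring $r$ carries $8r$ samples at equally spaced angles
  starting east, counter-clockwise (the standard LBP-style neighbourhood);
* $\Delta^{Ang}$ — consecutive-sample differences along each circle with
  wrap-around, sorted per ring;
* $\Delta^{Rad}$ — each circle sample minus the bilinear sample at the
  same angle one ring inward (ring 1 against the centre), sorted per ring.

Sorting makes the patterns invariant to rotations that map the sampling
lattice to itself; the difference patterns additionally cancel constant
intensity shifts. Each pattern is compressed by a fixed random matrix with
i.i.d. $\pm1$ entries (probability $1/2$ each): $f_X = RP_X\,x^X$, with
output dimension $a = 10(n-1)$ — the empirically established dimension for
these patch sizes. Distances between patterns are approximately preserved
(the compressed-sensing/Johnson–Lindenstrauss property), which the test
suite checks as a rank correlation above 0.8 between original and
projected pairwise distances.

One bank of five matrices is drawn once per analysis from a user seed
(default 42) and shared by every patch, plane and image. Without a shared
bank, descriptors would live in different random bases and could not be
compared or clustered.

### Hyperplanes of a cubic patch

A volume is tiled into non-overlapping $5\times5\times z$ patches
($z = \min(5, \text{slices})$). For the YZ family, a sampling plane is
built for every ordered pair (bottom column $i$, top column $j$),
$i,j\in\{0..4\}$: its rows are the five lateral positions and its columns
five samples along the 3D Bresenham line from $(i, y, 0)$ to
$(j, y, z-1)$ — 25 planes, vertical ($i=j$) planes included, since the
construction "between each column of the bottom slice and columns of the
top slice" reads most naturally as the full enumeration. The XZ family
swaps the roles of the axes; the XY family is the axial slices (all of
them when $z \le 5$, five evenly resampled ones otherwise). Bresenham
lines are computed by parametric rounding (round-half-to-even), which is
exactly symmetric under endpoint reversal; paths longer than five voxels
are subsampled at five evenly spaced indices, and for $z<5$ the line is
evaluated at five evenly spaced fractions, so every plane is a $5\times5$
grid.

Per family, the five functions of all planes are pooled per function,
histogrammed into 16 equal-width bins spanning the pooled range
(patch-local edges keep the descriptor self-contained and robust to
intensity scale; a degenerate range puts all mass in bin 1), L1-normalized
so patches with different plane counts stay comparable, and concatenated:
$16 \times 5 = 80$ values per family, $240$ for the three families. The
pseudo-3D variant applies only the axial sequence (80 values) and ignores
interslice correlations; comparing it with the full descriptor isolates
the value of the third-plane information.

### Numerical exactness

Rotation invariance of $f_G, f_S, f_C$ is tested as *bitwise* equality
under 90/180/270° patch rotations. This is achievable because circle
offsets and bilinear weights are constructed once for a first-octant base
set and propagated to the full circle by exact dihedral index
permutations, and each sample is evaluated as a fixed-order four-term
weighted sum. Two caveats are deliberate: constant-shift invariance of
$f_A, f_R$ holds only up to floating-point cancellation (tested at 1e-9),
and the axial-flip invariance of the plane families holds exactly for
$f_G, f_S, f_C, f_R$ but not for $f_A$ — flipping the slice order mirrors
each hyperplane, which negates signed angular differences. We keep the
signed convention (differences, not magnitudes) and test the four
functions for which the claim is true.

A constant patch deserves a note: its difference patterns are exactly zero,
so the $A$ and $R$ histogram blocks collapse into one bin, but the
intensity functions still take $a$ distinct values (the $\pm1$ row sums of
the projection matrix differ), so those blocks do not collapse.

## Image encoding

Patch descriptors are redundant; images are compared through global
encodings:

* **BOVW** — a $k$-means codebook (k-means++ seeding, 10 restarts, Lloyd
  iterations, fixed seed) and hard nearest-centroid assignment with sum
  pooling: a count histogram of length $k$. Vocabulary size is chosen by
  the elbow of the SSE curve over candidates $\{32, 64, 96, 128, 160\}$.
  The elbow is automated as the maximum discrete second difference of
  $\log \mathrm{SSE}$ along the curve anchored at the $k=1$ total sum of
  squares: the log scale detects the collapse of the decay *rate*, which
  matches the visual "least $k$ after which SSE scarcely varies" reading
  and, unlike the raw-SSE second difference, can select the first
  candidate. A plot method still draws the arm for visual inspection.
* **Fisher vectors** — gradients of a diagonal-covariance GMM
  log-likelihood with respect to means and standard deviations, dimension
  $2GD$; the weight-gradient block is omitted, consistent with that
  dimension. Power (signed square root) and L2 normalization are applied
  by default, following common Fisher-vector practice, and can be turned
  off.

Inside cross-validation, codebooks are fit on the outer training folds
only (on at most 5000 sampled training descriptors — standard BOVW
practice that bounds runtime without materially changing centroids) and
reused for the held-out fold, so no information leaks from test images
into the vocabulary.

## HC/EC condensation metrics

The per-patch projected values are retained: $[f_G]_{CP_i}$ pooled over
all planes of patch $i$, and the concatenated $[f_{R,A}]_{CP_i}$. The HC
threshold is the minimum *non-zero* per-patch maximum (all-zero corner
patches of tilted nuclei are excluded); values strictly above it count as
HC, ties as EC, and

$$\frac{HC}{EC} = \frac{\sum [f]_{HC}}{\sum [f]_{Nucleus} - \sum [f]_{HC}}.$$

The intensity measure uses $f_G$; the aggregation (gradient) measure uses
$f_{R,A}$. Both are dimensionless and exactly scale-invariant.

One design decision departs from a literal reading: the ratio is computed
on **absolute** projected values by default. A sign-symmetric $\pm1$
projection makes roughly half of the pooled mass negative, so the EC
denominator $\sum[f]_{Nucleus} - \sum[f]_{HC}$ of the literal form is
almost surely large and negative for any real volume and any bank seed —
the ratio would be meaningless. Magnitudes preserve everything the measure
is meant to capture (how much of the signal mass clears a
brightest-dim-patch threshold), keep all the worked examples (which are
all-positive), the degenerate cases and the exact scale invariance.
`use_abs = FALSE` restores the literal behaviour and flags a non-positive
denominator as invalid instead of returning it.

Group differences are assessed with the two-sided Wilcoxon rank-sum test
at the 1% level (normal approximation with tie correction; the
z-statistic is reported so the direction of the median shift is explicit).

## Classification protocol

Cells from the same 3D image share a fold (grouped 10-fold CV; whole
images are assigned greedily by size to the smallest fold, approximately
balancing cell counts). Per fold: codebook on training images, per-fold
standardization, RBF gamma from the median of pairwise squared distances
among 100 sampled training rows (the standard median/sigest-style
heuristic — the cited heuristic search is not specified further), and a
C-SVM with the default constant $C=1$. Decision values feed the ROC/AUC;
F1, precision and recall use the sign of the decision value. No SVM
library is available in the target environment, so the package solves the
C-SVM dual directly by coordinate descent on the bias-augmented kernel
$K+1$; on the package's problem sizes (tens to hundreds of cells) this
converges in milliseconds and is exact for the regularized-bias
formulation.

Model families are compared with the Kruskal–Wallis test at 1% (mean ranks
and comparison intervals are reported for plotting); the 3D-versus-pseudo
question uses a one-sided pooled two-sample t-test at 5% of the null
"pseudo-3D is at least as good".

## The phantom generator: what it emulates and what it does not

`generate_nucleus()` builds a DAPI-like cell object: an ellipsoidal
nucleus (semi-axes 26, 22, 6.5 voxels in a 64×64×15 volume, matching
cropped ~64×64 cell objects up to 15 slices, with z much coarser than xy)
over a flat background (level 8); inside the mask, a euchromatin base of
level 100 plus a Gaussian-smoothed noise field (sigma 1.5 voxels, sd 15)
emulating diffuse chromatin; HC foci as hard spheres (radius 2) with
1-voxel Gaussian-feathered edges — feathering makes the gradient-based
aggregation measure respond to focus sharpness, not just brightness —
whose intensity is multiplied by a gain; additive Gaussian noise (sd 5)
clipped at zero; quantization to integers so 16-bit TIFF output
round-trips bit-exactly. Volumes outside the mask are exactly the
background level. The `condensed` preset uses 18 foci at gain 3.0, the
`open` preset 6 foci at gain 1.6 — chosen once as a plausible condensation
contrast (numerous bright puncta versus sparse faint ones) and not tuned
against any test outcome. A 60-slice deep preset is available through
`shape` to exercise the z-resampling paths.

The generator does **not** simulate a PSF, Poisson shot noise, anisotropic
blur, nucleoli channels, touching nuclei or staining gradients. A green
phantom test therefore establishes that the pipeline recovers a
*constructed* condensation contrast end to end — descriptor, encoding,
classifier and metrics all moving in the right direction — not that it
reproduces any particular real-data accuracy.

## Degenerate inputs and tie rules

* Sorting ties keep arbitrary order (sorted multisets are unaffected).
* Histogram values exactly at the top edge fall in bin 16; degenerate
  ranges put all mass in bin 1.
* `hc_threshold` errors on all-zero maxima (e.g. a constant volume has no
  gradient signal at all); an empty HC set gives ratio 0; a zero EC sum
  gives `+Inf` with a warning.
* BOVW assignment ties go to the lowest centroid index; elbow ties to the
  smallest candidate.
* Single-class folds are skipped with a warning and excluded from means.
* Single-slice volumes are accepted everywhere (the 2D case): description
  falls back to the axial sequence.
* Bresenham rounding halves follow round-half-to-even, making paths
  exactly reversal-symmetric.

## Known limitations

* The hyperplane construction is fixed to lateral side 5 ($n=2$); larger
  patches are supported in the 2D SRP core only.
* HC/EC ratios depend (weakly) on the bank seed; comparisons are only
  meaningful within one bank, which is why one bank serves a whole run.
* The SSE elbow on small or unstructured descriptor sets can be flat; the
  tie rule then returns the smallest candidate.
* The TIFF layer reads uncompressed single-channel baseline files only —
  sufficient for microscopy stacks exported without compression, not a
  general TIFF reader.
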