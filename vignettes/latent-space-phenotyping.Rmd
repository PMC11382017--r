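---
title: "Latent-space phenotyping: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space phenotyping: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
models, which knobs matter, what the synthetic world does and does not
establish, and where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

# The pipeline

A field trial of `m` accessions is grown under two irrigation treatments
with replicates; each plot is observed as an RGB image and a digital
surface model (DSM), and five biomass traits (dry weight DW, main stem
length SL, node count NN, branch count NB, plant height PH) are measured
destructively. The package estimates traits from imagery through a
30-dimensional latent bottleneck, treats the latent principal components as
phenotypes in their own right, and asks how well both traits and latent PCs
can be predicted from genome-wide markers.

## Vegetation segmentation

A pixel is vegetation when `VDVI = (2G - R - B)/(2G + R + B) > 0.057` and
its green component is at least 10 (near-black pixels are removed however
green-dominated their chromaticity is). Both constants are published values
carried as defaults, not re-tuned here. A pixel with `R = G = B = 0` has an
undefined VDVI; we define it as 0 and never class it as vegetation — any
convention works because the green floor already excludes such pixels.

## Geometric standardization

The published preprocessing aligns "position and orientation" by an affine
transform without further detail. We use the minimal rigid interpretation:
translate the vegetation-mask centroid to the canvas center and rotate the
mask's second-moment principal axis to horizontal, with nearest-neighbour
resampling (no scale change, identical transform for RGB, DSM, and mask).
Near-isotropic masks skip the rotation, since their principal axis is
numerically meaningless. Half-pixel offsets are rounded upward consistently
(`floor(x + 0.5)`) so that translated copies of a scene standardize
identically. How ground height is removed from the DSM is also unstated; we
subtract the median DSM value over off-mask (soil) pixels, the smallest
assumption that makes canopy heights comparable across plots.

## The network

The published architecture is described only as 14 layers of conv /
maxpool / linear type with ReLU, batch normalization, and dropout, a
30-dimensional penultimate vector, and a purely linear 5-output head; the
exact stack lives in supplementary material that is not available. Our
default reconstruction satisfies every stated constraint: five
conv(3×3)–batchnorm–ReLU–maxpool(2×2) blocks (8, 16, 32, 32, 64 filters),
flatten, two ReLU+dropout linear layers (128, 64), a linear 30-unit feature
layer, and the linear head — 5 conv + 5 batchnorm + 2 linear + feature
layer + head = 14 weighted layers, all overridable through `model_spec()`.
RGB and DSM are fused early, by channel concatenation (the simplest
published-compatible choice).

Training follows the published schedule: Adam, learning rate 0.001, batch
size 128 (desk-scale runs use smaller batches), MSE over the five
normalized traits jointly, 100 epochs with reduce-on-plateau (factor 0.5,
patience 5, min 1e-6), returning the checkpoint with the lowest validation
MSE. The paper selects this checkpoint on the same split it reports; we
replicate that protocol in `crossvalidate()` (the held-out fold doubles as
the validation split) because fidelity was judged more important than the
small optimism it introduces; the leakage is confined to model selection,
not to weights.

When the features are standardized is unstated in the source. We place a
*non-affine* batch normalization on the feature layer, so features are
approximately standardized during training, and recompute exact mean/SD on
the reference set afterwards (`extract_features()`), re-expressing the head
as `W* = diag(s) W`, `b* = b + W'm`. This keeps the head identity
`Ŷ = XW* + 1b*'` exact — the algebraic anchor for everything downstream —
while honoring the mean-0/variance-1 statement.

## Latent phenotypes

PCA of the standardized features gives `S = (X − 1c')E`; because `E` is
orthogonal, `W' = E'W` with bias `b' = b + W'c` reproduces the head exactly
with all 30 components (`pc_head()` carries the centering so the identity
holds on held-out rows too). Eigenvector sign is the only indeterminacy PCA
introduces, so alignment across cross-validation trials flips whole `W'`
rows only, choosing the flip that best agrees with the running modal sign
pattern, ties toward no flip. PCs are matched across trials purely by rank
of explained variance; if two components swap ranks between trials their
weights are averaged across *different* axes — a real limitation we flag
rather than hide, since the source describes no permutation matching
either. The default of aligning/annotating 3 leading components follows the
source's interpretive focus. Note that inside the prediction sweep
(`sweep_components()`), sign alignment is a mathematical no-op: flipping an
eigenvector negates both the predicted score and the `W'` row, leaving
`S̃W'` unchanged — so the sweep does not perform it.

## GBLUP

`y = 1μ + Zg + e`, `g ~ MVN(0, Gσ²_g)`, `e ~ MVN(0, Iσ²_e)`, with
`G = XX'/c`, `c = 2Σp(1−p)`. The cited normalization constant is
VanRaden's, whose derivation assumes column-centered scores, so centering
(by `2p − 1`) defaults on; the literal uncentered formula is available via
`center = FALSE`. REML is solved by a deterministic 1-D search over
`log10(σ²_g/σ²_e)` on the eigenbasis of `ZGZ'` — one `O(n³)`
decomposition, then `O(n)` per likelihood evaluation. Predictions for
unobserved accessions are the BLUP `σ²_g G Z'V⁻¹(y − 1μ)`, identical to the
conditional-MVN formula (asserted against an independent implementation in
the tests). LD-aware imputation is out of scope; missing calls are
mode-imputed, adequate for the MCAR missingness the generator produces.
Cross-validation folds partition *accessions*, not plots: plot-wise folds
would leak replicate information through `G` (the source is ambiguous; this
is the conservative reading).

## Trait prediction from predicted PCs

Per fold: features are re-standardized with training-fold statistics, PCA
is fitted on training-fold features only, one GBLUP per component and
treatment predicts held-out accessions' scores, and `Ỹ = S̃W'_l + 1b'`
reconstructs traits for `l = 1..10`. The source is ambiguous about whether
fold-specific CNNs or a single model feed this analysis; we accept any
`latent_features` object, so both readings are expressible, and the
leakage-free fold-local PCA is always enforced (the test suite audits that
held-out rows never enter scaling, PCA, or GBLUP fitting).

# The synthetic world

No accession, image, or genotype from the motivating study is available, so
every input is generated (`simulate_field()`), with the causal structure
the pipeline assumes: genotype → breeding value → trait → canopy
appearance.

**Genotypes.** Allele frequencies are uniform on `maf_range`; each
accession receives two independent gametes (Hardy–Weinberg proportions)
from a latent Gaussian shared within LD blocks (`ld_block_size = 10`,
`ld_rho = 0.95` by default). The LD is essential realism, not decoration: a
scaled-down panel of 1,000 markers emulating a multi-million-SNP panel of a
selfing species must have far fewer *effective* genome segments than
markers, because genomic-prediction accuracy is governed by
`sqrt(n h² / (n h² + Me))`. With independent markers (`ld_block_size = 1`)
`Me ≈ 1000` exceeds the panel size and GBLUP accuracy is structurally
capped near 0.2–0.3 — no implementation could reach realistic accuracy in
that world.

**Traits.** 50 causal SNPs receive effect vectors drawn iid from a
multivariate normal with the configured 5×5 genetic correlation (default
0.5 everywhere), giving the traits a shared oligogenic architecture. Per
trait the genetic score is rescaled so the additive variance is exactly
`h²·σ²` and plot residuals supply the rest; drought multiplies both
components (defaults 0.6–0.9 per trait), producing uniformly lower values
under drought with unchanged realized heritability. Trait means/SDs
(60±20 g, 90±15 cm, 15±3, 6±2, 80±15 cm) are documented stand-ins — the
source reports no per-plot summary statistics to anchor them. Default
heritabilities (0.5–0.7) are in the range typical for biomass traits in
replicated trials.

**Imagery.** The renderer draws a soil background whose green channel is
constructed as a sub-unit fraction of `(R+B)/2`, making soil VDVI ≤ 0
(below the 0.057 threshold with margin, for any palette draw); a canopy
ellipse whose pixel area is monotone in DW; a height dome whose maximum
equals PH in meters; brightness sub-blobs whose count tracks `NN + NB`
(texture granularity); and a handful of near-black pixels (green < 10,
capped at 1% of the canopy) to exercise the dark-pixel filter. The ground
plane is exactly flat at height 0.

**What a green test establishes — and what it does not.** The generator
contains no occlusion between neighboring plots, no radiometric or SfM
reconstruction artifacts, no lodging, no within-canopy height texture, and
its trait-to-appearance map is far more direct than nature's. Green tests
therefore establish that the *pipeline machinery* is correct (exact
algebraic identities, oracle-matched mixed models, leakage-free
cross-validation, and the qualitative orderings the causal structure
implies) — not that the published real-data accuracies are reproduced;
those data are unavailable and their headline numbers are explicitly not
targets.

# Numerical choices

- Batch normalization uses biased batch variance, momentum 0.1, and
  `eps = 1e-5`, identically in training statistics and inference.
- Feature SDs below 1e-12 are replaced by 1 (dead units); their
  contribution moves into the bias, preserving the head identity.
- PCA eigenvalues below `1e-12 × max` trigger a rank-deficiency warning and
  are clipped at 0; the proportion of variance is renormalized over the
  clipped spectrum.
- REML searches `log10(σ²_g/σ²_e)` in `[-6, 6]`; hitting either end sets a
  `boundary` flag rather than failing (with a single observation per
  accession and an unstructured panel the ratio is weakly identified —
  replicates are what identify it, which is why the acceptance world uses
  the study's 2-replicate design).
- Modal genotype imputation breaks ties toward the lower score,
  deterministically.
- `pearson()` returns `NA` (never an error) for degenerate folds; CV
  summaries count and exclude them.
- Fold assignment, weight initialization, shuffling, and dropout all derive
  from explicit seeds; two runs with the same seeds are identical in
  single-threaded mode.

# Known limitations

- PC matching across CV trials is by explained-variance rank only; swapped
  ranks mis-pair components during weight averaging.
- The checkpoint-selection leakage of the published protocol is reproduced
  by design in `crossvalidate()`.
- The renderer's monotone trait encodings make image-based estimation
  easier than real canopies; accuracy levels on synthetic data are not
  comparable to field accuracies, only orderings and identities are
  meaningful.
- Early fusion is the only fully wired RGB+DSM combination; a two-branch
  late-fusion variant would require a second conv trunk.
- The VCF interface covers only biallelic GT records written by this
  package.
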