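---
title: "Quantized self-supervised localization representations: models and methods"
author: "cytovq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantized self-supervised localization representations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the engineering decisions behind
`cytovq`: what the model assumes, what every tunable parameter means, what
the synthetic data generator does and does not emulate, and where the
design was genuinely open.

## 1. The modelling idea

Protein localization is a visual phenotype: two proteins that traffic to
the same compartment produce images that look alike up to cell pose and
noise. `cytovq` exploits this with two pretext tasks that require no
localization labels at all:

1. **Reconstruction.** A two-level vector-quantized autoencoder compresses
   each crop through discrete codebooks and reconstructs it. Quantization
   forces the encoder to spend its capacity on recurring image motifs.
2. **Protein identification.** Classifier heads must recognise *which*
   protein produced the crop from the quantized representations alone.
   Because each protein's images share only their localization signature,
   the representation that solves this task is a localization
   representation.

The byproduct representations — not the classifier — are the output. The
global level (4 × 4 grid) captures large-scale organisation; the local
level (25 × 25) captures texture-scale motifs whose codebook indices form
interpretable per-protein *feature spectra*.

Assumptions worth stating: crops are centered on nuclei, so the nuclear
frame of reference is approximately aligned across crops; intensity is
informative only up to a per-field min–max normalization; one crop shows
one dominant cell; and each protein id maps to a single localization
signature (multi-localizing proteins blur this, which is visible in their
spectra rather than fatal).

## 2. Architecture and its contracts

The normative contracts are the latent shapes, not a specific layer list:
input `h × w × 2` → local latent `h/4 × w/4 × 64` (VQ1) → global latent
`4 × 4 × 576` (VQ2). The backbone that realises them here is a compact
stack of 3 × 3 convolutions (stride 2 for each halving, ReLU
nonlinearities, a linear final convolution per encoder), with
nearest-neighbour resizes in the decoders; `mselyr1` is the resize +
convolution stage that adapts `decoder2`'s output back to `encoder1`'s
output dimensions. Backbones are a configuration detail (`width` sets the
channel budget); anything that satisfies the latent contracts slots in.

The whole network, including backward passes, is vectorised base R: each
convolution is evaluated as one GEMM per kernel offset, so the heavy
lifting stays in BLAS. This keeps the package dependency-free on the
modelling side and fully reproducible from source.

### Split quantization

Quantizing a 4 × 4 grid of 576-dimensional vectors against 2,048 codes
gives only 16 quantized vectors per image, each very high-dimensional; in
practice a handful of codes capture everything and codebook perplexity
collapses. Split quantization divides each channel vector into 9
contiguous 64-dimensional subvectors quantized against one shared
codebook: 144 quantized vectors per image at identical spatial pooling.
The package's acceptance run measures the effect at desk scale (a 32-code
model): mean final-epoch global perplexity ≈ 4 with splitting versus ≈ 1.5
without (5 seeds, 2 epochs); at 15 epochs the split-quantized codebook
sits near perplexity 10 of 32.

### Quantizer conventions

* Nearest codes by Euclidean distance; ties break toward the lowest code
  index (`max.col(ties.method = "first")` on the negated distances), so
  quantization is deterministic.
* Codebook indices are **1-based** throughout, following R convention.
* Codebooks update by exponential moving average (decay 0.99) over
  assigned vectors, with the straight-through estimator for the encoder
  and a commitment coefficient of 0.25 — the standard settings of the
  VQ-VAE literature, exposed in `model_config()`. Counts and sums decay at
  the same rate, so a code with no recent assignments keeps its value:
  dead codes are left in place and surface as low perplexity rather than
  being silently re-seeded.
* The six loss terms are weighted 1, 1, 0.25, 0.25, 1, 1
  (reconstructions, commitments, cross entropies); relative weights are
  not settled in the literature this package follows, so they default to
  uniform with the commitment coefficient folded into the VQ terms.

## 3. Preprocessing

* **Projection**: maximum intensity over z, then 2 × 2 block-mean
  downsampling (the block mean is anti-aliased and constant-preserving;
  the downsampling operator is otherwise unconstrained).
* **Nucleus segmentation**: Gaussian low-pass (σ = 10 px) + minimum
  cross-entropy (Li) threshold for the background mask, then the
  LoG-refinement: the Laplacian-of-Gaussian response (σ = 5 px) is
  negative over bright blobs and positive over the neck between touching
  nuclei, so thresholding it at zero splits under-segmented pairs;
  closing (disk radius 4, the minimum that closes intra-nuclear gaps) and
  hole filling repair texture holes; re-masking restores true holes; and
  local-minima regions of the LoG response (lowest 1 percentile) that
  straddle the mask's background are removed. A minima region "partially
  overlaps" background when it has at least one pixel on each side. The
  σ values and the percentile are empirical; defaults were chosen on
  synthetic scenes (they resolve pairs with edge gaps ≳ 8 px at 512 px
  scale) and are fully configurable.
* **Signed distance**: +distance-to-boundary inside nuclei, −distance
  outside, each side normalized by its own maximum so the channel spans
  [−1, 1] and the most interior nuclear pixel is +1.
* **Crops**: one window per nucleus, centered on the integer-rounded
  centroid; windows that would cross the field border are skipped.
  Neighbouring cells naturally appear in a window — that context is part
  of the signal. Denser tilings are possible but not default.
* **Normalization scope**: fluorescence min–max per field of view (before
  cropping), so crops from one field share a contrast scale; per-crop
  normalization is available (`normalize_per = "crop"`).

## 4. The synthetic data generator

The generator emulates what matters to the method: two-channel scenes with
elliptical nuclei (semi-axes 15–30 px at 512 px scale, matching epithelial
cell nuclei at this working resolution), seven localization families
(nuclear-diffuse, nucleolar, chromatin-like, cytoplasmic-diffuse,
punctate, reticular, filamentous) rendered in their correct compartments,
per-protein pattern parameters drawn once and shared across a protein's
images, and Poisson shot noise (200 photons at unit intensity) plus
Gaussian read noise (σ = 0.01) — mild enough that families stay separable,
as in a well-exposed confocal acquisition. All randomness flows through
explicit seeds (child seeds per protein/image), so datasets are
bit-reproducible and the caller's RNG stream is untouched.

What it does **not** emulate: photorealistic optics (PSF anisotropy,
depth-dependent blur), cell-cycle and morphology heterogeneity,
multi-localizing proteins, batch effects, or segmentation-hostile tissue
contexts. Passing tests on this data therefore demonstrate that the
implementation is correct and that the pipeline's claims hold under
controlled conditions — not that real-microscopy performance figures
transfer.

## 5. Training protocol

8:1:1 train/validation/test split at crop level (as the method's reference
protocol states). Crop-level splitting lets near-duplicate crops from one
field span partitions, which flatters validation scores on tiny synthetic
sets; protein-stratified and the split helper's options exist for when
that matters, but the default follows the protocol rather than silently
"fixing" it. Augmentation is random 90° rotations and flips (exact pixel
permutations — no interpolation loss). Adam starts at 4 × 10⁻⁴; "no
improvement" means the best validation loss has not dropped by more than
10⁻⁶ (absolute), the learning rate decays ×0.1 after 4 such epochs
(plateau counter resets on decay), and training stops after more than 12.
`schedule_step()` is a pure function of the loss history and is tested
against an independent counter simulation. Batch size (64) and the epoch
cap are configuration, not claims.

## 6. Evaluation

* **Clustering score.** `Γ` = robust spread of class centroids / median of
  within-class robust spreads. The robust spread of an m-dimensional point
  set is defined here as 1.4826 × the median Euclidean distance to the
  coordinate-wise median — the definition reduces to the consistency-scaled
  MAD in 1D and tolerates rotations, and it is recorded in every
  `score_report` for auditability. Γ is translation- and scale-invariant;
  a degenerate denominator (all classes collapsed) raises an error rather
  than returning infinity, because model comparisons need finite scores.
  Points are per-image embeddings by default; scores are computed on 2D
  UMAP coordinates of the quantized global representation (both are
  choices the field leaves open; pre-quantization and per-protein-median
  modes are flags).
* **UMAP**: Euclidean metric, 15 neighbours, min_dist 0.1, fixed seed,
  single-threaded so runs are exactly reproducible.
* **Group separation** uses the two-sided Mann–Whitney U test on a stated
  1D reduction (projection onto the axis joining the two groups' robust
  centers); an all-tied input returns p = 1 with a warning.

## 7. Feature spectra

Spectra are raw occurrence counts of local codebook indices over all
images of a protein (row sums equal positions × images exactly);
frequency normalization is a flag for unbalanced image counts. Feature
profiles (columns) are correlated with Pearson; a constant profile
correlates 0 with everything and 1 with itself, keeping downstream
rankings total. Features are ordered by average-linkage agglomerative
clustering on the Euclidean distances between correlation-matrix rows
(the defaults of the common clustered-heatmap tools), and the ordering is
the dendrogram leaf order. Organelle prediction correlates a query
spectrum against per-category consensus (mean) spectra, leaving the query
protein out of its own categories; complex analysis asks whether a
protein's best-correlated neighbour shares a complex annotation. Manual
segmentation of the ordered spectrum into named feature clusters is
supported only as user-supplied breakpoints — it is a curation act, not a
computation.

## 8. Numerical choices and degenerate inputs

* Li thresholding iterates on a shifted strictly-positive copy of the
  image (tolerance 10⁻⁶ on the threshold) and returns the image value for
  constant input.
* Constant fluorescence crops normalize to zeros with a warning; an empty
  nucleus mask yields a uniform −1 distance map with a warning.
* `perplexity()` rejects all-zero counts; `split_quantize()` validates
  channel divisibility and code dimension.
* He initialisation for all weights; codebooks start from N(0, 0.5²).
  Untrained models already satisfy every shape and loss-positivity
  contract.
* Desk-scale problem sizes used by the test suite and the acceptance
  script (5 proteins, 256 px fields, 64 px crops, 32 codes, ≤ 15 epochs)
  were chosen so the full pipeline — including the split-vs-standard
  quantization comparison over 5 seeds — completes in minutes on one CPU
  while leaving the tested effects (above-chance identification,
  family-separating Γ, the perplexity gap) far from their thresholds.

## 9. Known limitations

* The backbone is a compact CNN, not an EfficientNet split; at
  dataset scale the published absolute clustering scores require the
  original corpus and GPU training and are out of scope here.
* Crop-level splitting (the default, above) can leak near-duplicates
  between partitions on small synthetic sets.
* No batch-effect correction, no anomaly rejection, no 3D (non-projected)
  modelling; the volume mode exists to exercise the projection step.
* UMAP and Γ are evaluated per-image; per-protein aggregation changes the
  absolute scale of Γ (a mode is provided, but scores across modes are
  not comparable).
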