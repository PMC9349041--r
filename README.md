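# cytovq

Self-supervised, vector-quantized representations of protein subcellular
localization from fluorescence microscopy.

## The problem

Imaging collections that tag thousands of proteins in live cells produce far
more images than curators can annotate, and manual labels (nucleolus,
ER, vesicles, ...) flatten real differences that are visible in the pixels.
`cytovq` learns localization representations **without any localization
labels**: the only supervision is the opaque identity of the tagged protein
in each image. The package is written for computational biologists who want
to map localization landscapes, compare pattern families, or screen for
proteins with similar trafficking — on their own images or on fully
synthetic benchmarks.

## The model

The core is a two-level vector-quantized autoencoder (VQ-VAE-2 family) with
a protein-identification pretext task. A crop `x` (100 × 100 × 2 pixels:
protein fluorescence plus the signed distance transform of the nucleus
mask) is encoded twice:

* `encoder1(x)` → **local latent** `z1` (25 × 25 × 64), quantized by
  codebook VQ1 (2,048 codes × 64 dims);
* `encoder2(z1)` → **global latent** `z2` (4 × 4 × 576), quantized by VQ2
  with **split quantization**: each 576-vector is split into 9 contiguous
  64-dim subvectors, each quantized against the same codebook. Splitting
  multiplies the number of quantized vectors per image without changing the
  spatial pooling, which keeps codebook use (perplexity,
  `exp(−Σ p_k log p_k)`) high where standard VQ collapses.

`decoder2` reconstructs `z1` from the quantized global latent (via the
dimension-adapting `mselyr1` stage); `decoder1` reconstructs the image from
the quantized local latent concatenated with the resized global
representation; two MLP heads (`fc1`, `fc2`) predict the protein identity
from each quantized representation. The training loss is the weighted sum
of two reconstruction MSEs, two categorical cross entropies, and two
commitment terms (coefficient 0.25); codebooks follow exponential-moving-
average updates (decay 0.99) with straight-through gradients. Optimization
is Adam (initial learning rate 4 × 10⁻⁴) with ×0.1 decay after 4 epochs
without validation improvement and early stopping after more than 12.

Downstream, the package provides:

* **UMAP maps** of the global representation (Euclidean metric, 15
  neighbours, min_dist 0.1) and the robust clustering score
  `Γ = σ*({μ*(C_j)}) / μ*({σ*(C_j)})`, where `μ*` is the coordinate-wise
  median and `σ*` is 1.4826 × the median Euclidean distance to it — the
  robust ratio of between-class spread to within-class spread;
* **feature spectra**: per-protein histograms of local codebook indices,
  ordered by hierarchical biclustering of the feature-profile correlation
  matrix, with leave-one-out organelle prediction (best-correlated
  consensus spectrum) and nearest-neighbour protein-complex analysis;
* a **synthetic scene generator** (7 localization pattern families,
  elliptical nuclei, Poisson/Gaussian noise) and the full preprocessing
  chain: max-intensity projection, 2× downsampling, LoG-refined nucleus
  segmentation with minimum cross-entropy (Li) thresholding, signed
  nuclear distance transform, per-nucleus 100 × 100 crops.

Everything — including the convolutional encoders/decoders and their
backward passes — is implemented in vectorised base R, so the package runs
anywhere R runs.

## Worked example

Desk-scale benchmark: 5 synthetic proteins spanning 5 localization
families, 64 × 64 crops, a 32-code model, 15 epochs on one CPU (~3 min).

```r
library(cytovq)

cfg <- synth_config(n_proteins = 5, images_per_protein = 6, fov_size = 256,
                    nuclei_per_fov = c(3, 5),
                    family_of = c("NUCLEAR_DIFFUSE", "PUNCTATE", "CYTO_DIFFUSE",
                                  "NUCLEOLAR", "RETICULAR"), seed = 7)
crops <- preprocess_dataset(generate_dataset(cfg), crop_size = 64)
crops
#> <crop_set> 92 crops of 64 x 64 x 2

model <- build_model(
  model_config(input_shape = c(64, 64, 2), n_classes = 5, n_codes = 32,
               code_dim = 16, n_splits = 4, classifier_hidden = 64, width = 16),
  seed = 2)
model
#> <cytovq_model> input 64x64x2 | local 16x16x16 | global 4x4x64 | 32 codes x 16 dims, 4 split(s)

fit <- train_model(model, crops,
                   train_config(batch_size = 32, max_epochs = 15, seed = 3))
tail(fit$history[, c("epoch", "train_loss", "val_loss", "global_perplexity")], 3)
#>    epoch train_loss val_loss global_perplexity
#> 13    13   2.103587 2.262691          9.797609
#> 14    14   2.199233 2.405738         10.027770
#> 15    15   2.060167 1.936058         10.478298

emb <- extract_representations(fit$model, crops, "global")
xy  <- reduce_umap(emb, umap_params(seed = 11))
clustering_score(xy, crops$index$family)
#> <score_report> gamma = 3.027 (centroid spread 4.833 / median within 1.597)
```

The training loss falls, the 32-code global codebook stays well used
(perplexity ≈ 10 with split quantization; it collapses towards 1 without),
and the family labels — never shown to the model — separate in the UMAP
with a clustering score of about 3, far above what permuted labels achieve.
Feature spectra for these crops come from
`spectrum_matrix(extract_representations(fit$model, crops, "local"), n_codes = 32)`.

A command-line wrapper with the same pipeline stages
(`synth`, `preprocess`, `train`, `embed`, `score`, `spectra`) is installed
at `inst/cli/cytovq.R`.

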