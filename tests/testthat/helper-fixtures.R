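# Shared fixtures, built in code at test time.

## 5 proteins spanning 5 families, 256 px FOVs, mild noise: the standard
## desk-scale dataset for pipeline tests
tiny_dataset_config <- function(images_per_protein = 6, seed = 7) {
  synth_config(
    n_proteins = 5, images_per_protein = images_per_protein, fov_size = 256,
    nuclei_per_fov = c(3, 5),
    family_of = c("NUCLEAR_DIFFUSE", "PUNCTATE", "CYTO_DIFFUSE",
                  "NUCLEOLAR", "RETICULAR"),
    seed = seed)
}

tiny_model_config <- function(...) {
  model_config(input_shape = c(64, 64, 2), n_classes = 5, n_codes = 32,
               code_dim = 16, n_splits = 4, classifier_hidden = 64,
               width = 16, ...)
}

## even smaller: 32 px crops and an 8-channel latent, for fast trainer tests
micro_model_config <- function(...) {
  model_config(input_shape = c(32, 32, 2), n_classes = 3, n_codes = 8,
               code_dim = 8, n_splits = 2, classifier_hidden = 16,
               width = 8, ...)
}

micro_cropset <- function(seed = 5) {
  cfg <- synth_config(n_proteins = 3, images_per_protein = 3, fov_size = 128,
                      nuclei_per_fov = c(2, 3),
                      family_of = c("NUCLEAR_DIFFUSE", "PUNCTATE", "CYTO_DIFFUSE"),
                      seed = seed)
  preprocess_dataset(generate_dataset(cfg), crop_size = 32)
}

## memoised tiny crop set (the preprocessing is the slow part)
tiny_cropset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- preprocess_dataset(generate_dataset(tiny_dataset_config()),
                                   crop_size = 64)
    }
    cache
  }
})

## scene with two nuclei separated by a small gap (px along x, between the
## ellipse edges) that the plain intensity threshold cannot resolve
touching_nuclei_scene <- function(gap = 8, side = 256) {
  cx2 <- 100 + 20 + gap + 20          # x semi-axes are 20 px
  m1 <- cytovq:::ellipse_mask(side, 128, 100, 22, 20, 0)
  m2 <- cytovq:::ellipse_mask(side, 128, cx2, 22, 20, 0)
  truth <- matrix(0L, side, side)
  truth[m1] <- 1L
  truth[m2] <- 2L
  nuclear <- matrix(0, side, side)
  nuclear[m1] <- 0.9
  nuclear[m2] <- 0.85
  nuclear <- as.matrix(EBImage::gblur(nuclear, 1.5))
  list(nuclear = nuclear, truth = truth)
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

## best IoU between each truth nucleus and any predicted label
recovery_ious <- function(pred, truth) {
  sapply(seq_len(max(truth)), function(k) {
    tm <- truth == k
    labs <- setdiff(unique(pred[tm]), 0)
    if (length(labs) == 0) return(0)
    max(sapply(labs, function(l) mask_iou(pred == l, tm)))
  })
}

## synthetic 5-family spectra: each family concentrates its counts on its
## own block of codebook indices, proteins add Poisson resampling noise
synth_family_spectra <- function(n_per_family = 6, n_codes = 40, seed = 3) {
  fams <- paste0("F", 1:5)
  base <- lapply(1:5, function(f) {
    prof <- rep(2, n_codes)
    prof[((f - 1) * 8 + 1):(f * 8)] <- 60
    prof
  })
  withr::with_seed(seed, {
    rows <- list()
    ann <- list()
    for (f in 1:5) for (p in seq_len(n_per_family)) {
      id <- sprintf("%s_p%02d", fams[f], p)
      rows[[id]] <- rpois(n_codes, base[[f]])
      ann[[id]] <- data.frame(protein_id = id, organelle = fams[f])
    }
    list(matrix = do.call(rbind, rows),
         annotations = annotation_table(organelle = do.call(rbind, ann)))
  })
}
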