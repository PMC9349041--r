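#' Annotation table
#'
#' Bundles protein-level ground truth: an organelle localization label per
#' protein and (optionally) protein-complex memberships.
#'
#' @param organelle Data frame with columns `protein_id`, `organelle`.
#' @param complexes Optional data frame with columns `protein_id`,
#'   `complex_id` (one row per membership; proteins may belong to several
#'   complexes).
#' @return Object of class `annotation_table`.
#' @export
annotation_table <- function(organelle = NULL, complexes = NULL) {
  if (!is.null(organelle)) {
    stopifnot(all(c("protein_id", "organelle") %in% names(organelle)))
  }
  if (!is.null(complexes)) {
    stopifnot(all(c("protein_id", "complex_id") %in% names(complexes)))
  }
  structure(list(organelle = organelle, complexes = complexes),
            class = "annotation_table")
}

#' Histogram of local codebook indices
#'
#' Counts how often each codebook index occurs over all positions of all
#' supplied index maps (typically: all images of one protein).
#'
#' @param index_maps List of integer matrices/arrays of 1-based codebook
#'   indices (a single map may be given directly).
#' @param n_codes Codebook size.
#' @return Integer count vector of length `n_codes`.
#' @export
index_histogram <- function(index_maps, n_codes) {
  if (!is.list(index_maps)) index_maps <- list(index_maps)
  idx <- unlist(lapply(index_maps, as.integer), use.names = FALSE)
  if (length(idx) && (min(idx) < 1 || max(idx) > n_codes)) {
    stopf("index out of range 1..%d", n_codes)
  }
  tabulate(idx, nbins = n_codes)
}

#' Per-protein feature spectrum matrix
#'
#' Builds the proteins x codebook-features count matrix: row p is the
#' histogram of local codebook indices over all images of protein p. Raw
#' occurrence counts by default; `normalize = TRUE` divides each row by its
#' sum (useful when proteins have unequal image counts).
#'
#' @param index_maps List of per-image index maps, or a local-level
#'   `embedding_set` from [extract_representations].
#' @param protein_ids One protein id per map (ignored when an
#'   `embedding_set` is supplied).
#' @param n_codes Codebook size.
#' @param normalize Divide rows by their sums.
#' @return Matrix `P x n_codes` with protein ids as row names.
#' @export
spectrum_matrix <- function(index_maps, protein_ids = NULL, n_codes,
                            normalize = FALSE) {
  if (inherits(index_maps, "embedding_set")) {
    protein_ids <- index_maps$protein_ids
    index_maps <- index_maps$index_maps
  }
  stopifnot(length(index_maps) == length(protein_ids))
  ids <- unique(protein_ids)
  mat <- t(vapply(ids, function(p) {
    index_histogram(index_maps[protein_ids == p], n_codes)
  }, numeric(n_codes)))
  rownames(mat) <- ids
  if (normalize) mat <- mat / pmax(rowSums(mat), 1)
  mat
}

## Pearson correlation with the constant-vector policy: a constant vector
## correlates 0 with everything else and 1 with itself
cor_constant_zero <- function(m, warn = FALSE) {
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    if (warn) warning("constant profiles present; their correlations are set to 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Pairwise correlation of feature profiles
#'
#' Pearson correlation between every pair of codebook-feature profiles (the
#' columns of the spectrum matrix), giving a features x features matrix in
#' which related or redundant codes show up as correlated blocks.
#'
#' @param matrix Spectrum matrix from [spectrum_matrix] (needs >= 3
#'   proteins).
#' @return `n_codes x n_codes` correlation matrix.
#' @export
feature_correlation <- function(matrix) {
  if (nrow(matrix) < 3) stopf("need >= 3 proteins to correlate profiles")
  cor_constant_zero(matrix)
}

#' Order codebook features by hierarchical biclustering
#'
#' Agglomerative clustering (average linkage, Euclidean distance between
#' rows of the correlation matrix); the feature ordering is the dendrogram
#' leaf order, which places features with similar profiles next to each
#' other.
#'
#' @param corr Feature correlation matrix from [feature_correlation].
#' @return Object of class `feature_ordering`: `order` (permutation of
#'   `1..K`) and `linkage` (the `hclust` tree, `NULL` for K = 1).
#' @export
bicluster_order <- function(corr) {
  if (any(!is.finite(corr))) stopf("non-finite entries in correlation matrix")
  k <- nrow(corr)
  if (k == 1) {
    return(structure(list(order = 1L, linkage = NULL), class = "feature_ordering"))
  }
  hc <- stats::hclust(stats::dist(corr, method = "euclidean"), method = "average")
  structure(list(order = hc$order, linkage = hc), class = "feature_ordering")
}

consensus_spectra <- function(matrix, annotations, leave_out = NULL) {
  ann <- annotations$organelle
  ann <- ann[ann$protein_id %in% rownames(matrix), , drop = FALSE]
  if (!is.null(leave_out)) ann <- ann[ann$protein_id != leave_out, , drop = FALSE]
  cats <- unique(annotations$organelle$organelle)
  out <- list()
  dropped <- character(0)
  for (cat_ in cats) {
    members <- ann$protein_id[ann$organelle == cat_]
    if (length(members) == 0) {
      dropped <- c(dropped, cat_)
      next
    }
    out[[cat_]] <- colMeans(matrix[members, , drop = FALSE])
  }
  if (length(dropped)) {
    warning(sprintf("categories emptied by leave-out and excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  do.call(rbind, out)
}

#' Predict localization from a feature spectrum
#'
#' Computes the consensus (mean) spectrum of every localization category —
#' excluding `leave_out` from its own categories — and ranks categories by
#' the Pearson correlation between the query spectrum and each consensus.
#'
#' @param spectrum Query spectrum (length `n_codes`).
#' @param matrix Spectrum matrix of annotated proteins.
#' @param annotations An [annotation_table] with organelle labels.
#' @param leave_out Protein id to hold out of the consensus computation.
#' @return Object of class `prediction_result`: `ranking` (data frame of
#'   `category`, `r`, sorted by decreasing correlation) and `true_rank`
#'   (rank of `leave_out`'s own category if it is annotated, else `NA`).
#' @export
consensus_and_predict <- function(spectrum, matrix, annotations,
                                  leave_out = NULL) {
  cons <- consensus_spectra(matrix, annotations, leave_out)
  if (is.null(cons) || nrow(cons) == 0) stopf("no categories with members")
  r <- vapply(seq_len(nrow(cons)), function(i) {
    if (stats::sd(cons[i, ]) == 0 || stats::sd(spectrum) == 0) return(0)
    stats::cor(spectrum, cons[i, ])
  }, numeric(1))
  ranking <- data.frame(category = rownames(cons), r = r)
  ranking <- ranking[order(-ranking$r), , drop = FALSE]
  rownames(ranking) <- NULL
  true_rank <- NA_integer_
  if (!is.null(leave_out)) {
    ann <- annotations$organelle
    truth <- ann$organelle[ann$protein_id == leave_out]
    if (length(truth) == 1 && truth %in% ranking$category) {
      true_rank <- which(ranking$category == truth)
    }
  }
  structure(list(ranking = ranking, true_rank = true_rank),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result> top:", x$ranking$category[1],
      sprintf("(r = %.3f)\n", x$ranking$r[1]))
  invisible(x)
}

#' Leave-one-out localization prediction accuracy
#'
#' Runs [consensus_and_predict] for every annotated protein in the matrix,
#' leaving it out of the consensus spectra, and reports the fraction whose
#' true category ranks within `top_k`.
#'
#' @param matrix Spectrum matrix.
#' @param annotations An [annotation_table].
#' @param top_k Ranks counted as correct (default 1).
#' @return List with `accuracy` and the per-protein `ranks`.
#' @export
loo_prediction_accuracy <- function(matrix, annotations, top_k = 1L) {
  ann <- annotations$organelle
  prots <- intersect(ann$protein_id, rownames(matrix))
  ranks <- vapply(prots, function(p) {
    pr <- suppressWarnings(
      consensus_and_predict(matrix[p, ], matrix, annotations, leave_out = p))
    pr$true_rank
  }, integer(1))
  list(accuracy = mean(ranks <= top_k, na.rm = TRUE),
       ranks = stats::setNames(ranks, prots))
}

#' Pairwise correlation of protein spectra
#'
#' Symmetric proteins x proteins Pearson correlation matrix over spectrum
#' rows. Constant rows correlate 0 with everything (with a warning) and 1
#' with themselves.
#'
#' @param matrix Spectrum matrix (>= 2 proteins).
#' @return `P x P` correlation matrix.
#' @export
pairwise_spectrum_correlation <- function(matrix) {
  if (nrow(matrix) < 2) stopf("need >= 2 proteins")
  cor_constant_zero(t(matrix), warn = TRUE)
}

#' Fraction of nearest spectral neighbours sharing a protein complex
#'
#' For each protein with complex annotations, finds its most-correlated
#' neighbour among the other annotated proteins. For every threshold `t`,
#' reports — among proteins whose best correlation exceeds `t` — the
#' fraction that share at least one complex with that neighbour. A
#' threshold no protein passes yields `NA`.
#'
#' @param matrix Spectrum matrix.
#' @param annotations An [annotation_table] with `complexes`.
#' @param thresholds Numeric vector of correlation thresholds.
#' @return Named numeric vector of fractions, one per threshold.
#' @export
neighbor_complex_fraction <- function(matrix, annotations,
                                      thresholds = c(0.8, 0.9, 0.95)) {
  cx <- annotations$complexes
  if (is.null(cx)) stopf("complex annotations required")
  prots <- intersect(unique(cx$protein_id), rownames(matrix))
  if (length(prots) < 2) stopf("need >= 2 proteins with complex annotations")
  cc <- suppressWarnings(pairwise_spectrum_correlation(matrix[prots, , drop = FALSE]))
  diag(cc) <- -Inf
  best_j <- apply(cc, 1, which.max)
  best_r <- cc[cbind(seq_along(prots), best_j)]
  shares <- vapply(seq_along(prots), function(i) {
    a <- cx$complex_id[cx$protein_id == prots[i]]
    b <- cx$complex_id[cx$protein_id == prots[best_j[i]]]
    length(intersect(a, b)) > 0
  }, logical(1))
  out <- vapply(thresholds, function(t) {
    sel <- best_r > t
    if (!any(sel)) NA_real_ else mean(shares[sel])
  }, numeric(1))
  stats::setNames(out, paste0("t", thresholds))
}
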