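#' UMAP parameters
#'
#' Defaults follow the reference UMAP implementation: Euclidean metric, 15
#' nearest neighbours, minimum distance 0.1.
#'
#' @param n_neighbors Nearest neighbours (>= 2).
#' @param min_dist Minimum embedding distance.
#' @param metric Distance metric.
#' @param seed Seed for the stochastic layout.
#' @return Object of class `umap_params`.
#' @export
umap_params <- function(n_neighbors = 15L, min_dist = 0.1,
                        metric = "euclidean", seed = 42L) {
  if (n_neighbors < 2) stopf("n_neighbors must be >= 2")
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 metric = metric, seed = as.integer(seed)),
            class = "umap_params")
}

#' Extract learned representations from a trained model
#'
#' Global level: the (quantized) coarse latent, flattened to one row per
#' crop. Local level: additionally retains the per-crop map of local
#' codebook indices, the raw material for feature spectra.
#'
#' @param model A trained [build_model] result.
#' @param cropset A `crop_set`.
#' @param level `"global"` or `"local"`.
#' @param quantized Use the quantized latent (default) or the
#'   pre-quantization encoder output.
#' @param batch_size Inference batch size.
#' @return Object of class `embedding_set`: `embeddings` (n x m matrix),
#'   `protein_ids`, and for the local level `index_maps` (list of integer
#'   matrices of 1-based codebook indices).
#' @export
extract_representations <- function(model, cropset,
                                    level = c("global", "local"),
                                    quantized = TRUE, batch_size = 64L) {
  level <- match.arg(level)
  cfg <- model$config
  if (quantized && !cfg$use_vq) quantized <- FALSE
  n <- length(cropset$crops)
  rows <- list(); maps <- list()
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    x <- crops_to_batch(cropset, b)
    out <- model_forward(model, x)
    if (level == "global") {
      z <- if (quantized) out$quant_global$quantized else out$latent_global
      rows[[length(rows) + 1]] <- t(matrix(z, prod(cfg$global_shape), length(b)))
    } else {
      z <- if (quantized) out$quant_local$quantized else out$latent_local
      rows[[length(rows) + 1]] <- t(matrix(z, prod(cfg$local_shape), length(b)))
      if (!is.null(out$quant_local)) {
        for (j in seq_along(b)) {
          maps[[b[j]]] <- out$quant_local$indices[, , 1, j]
        }
      }
    }
  }
  structure(list(embeddings = do.call(rbind, rows),
                 protein_ids = cropset$index$protein_id,
                 family = cropset$index$family,
                 index_maps = if (level == "local") maps else NULL,
                 level = level, quantized = quantized),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d points x %d features (%s%s)\n",
              nrow(x$embeddings), ncol(x$embeddings), x$level,
              if (x$quantized) ", quantized" else ""))
  invisible(x)
}

#' Project embeddings to 2D with UMAP
#'
#' @param embeddings An `embedding_set` or a numeric matrix.
#' @param params A [umap_params].
#' @return n x 2 coordinate matrix.
#' @export
reduce_umap <- function(embeddings, params = umap_params()) {
  X <- if (inherits(embeddings, "embedding_set")) embeddings$embeddings else embeddings
  if (nrow(X) <= params$n_neighbors) {
    stopf("need more points (%d) than n_neighbors (%d)", nrow(X), params$n_neighbors)
  }
  coords <- with_seed(params$seed,
    uwot::umap(X, n_neighbors = params$n_neighbors, min_dist = params$min_dist,
               metric = params$metric, n_threads = 1, n_sgd_threads = 0))
  unname(coords)
}

#' Robust center and spread of a point set
#'
#' The robust center is the coordinate-wise median. The robust spread is
#' `1.4826 * median(|x_i - center|_2)` — the consistency-scaled median
#' Euclidean distance to the robust center, which reduces to the scaled
#' median absolute deviation in one dimension.
#'
#' @param points n x m matrix (or numeric vector for 1D).
#' @return `robust_center`: length-m vector. `robust_spread`: scalar.
#' @export
robust_center <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stopf("empty point set")
  apply(points, 2, stats::median)
}

#' @rdname robust_center
#' @export
robust_spread <- function(points) {
  points <- as.matrix(points)
  ctr <- robust_center(points)
  d <- sqrt(rowSums(sweep(points, 2, ctr)^2))
  1.4826 * stats::median(d)
}

#' Robust clustering score
#'
#' Measures how well embedded points separate by class: the robust spread
#' of the class centroids divided by the median of the within-class robust
#' spreads. High values mean tight classes with well-separated centers.
#' The score is invariant to translation and global rescaling.
#'
#' @param points n x m matrix of embedded points.
#' @param labels Class assignment, one per row (>= 2 classes).
#' @return Object of class `score_report`: `gamma`, `centroid_spread`,
#'   `within_spreads` (named per class), and the robust statistic
#'   definitions used.
#' @export
clustering_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  stopifnot(nrow(points) == length(labels))
  cls <- unique(labels)
  if (length(cls) < 2) stopf("need at least 2 classes")
  centers <- vapply(cls, function(cl) robust_center(points[labels == cl, , drop = FALSE]),
                    numeric(ncol(points)))
  centers <- if (is.null(dim(centers))) matrix(centers, ncol = 1) else t(centers)
  within <- vapply(cls, function(cl) robust_spread(points[labels == cl, , drop = FALSE]),
                   numeric(1))
  num <- robust_spread(centers)
  den <- stats::median(within)
  if (den == 0) stopf("degenerate input: all classes have zero robust spread")
  structure(list(gamma = num / den, centroid_spread = num,
                 within_spreads = within,
                 robust_center = "coordinate-wise median",
                 robust_spread = "1.4826 * median Euclidean distance to center"),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> gamma = %.4g (centroid spread %.4g / median within %.4g)\n",
              x$gamma, x$centroid_spread, stats::median(x$within_spreads)))
  invisible(x)
}

#' Rank-sum separation of two groups of embedded points
#'
#' Two-sided Mann–Whitney U (Wilcoxon rank-sum) test of group separation.
#' Multivariate points are first reduced to 1D by projecting onto the axis
#' joining the two groups' robust centers; 1D input is used as is. The
#' reported U counts pairs where a group-A value exceeds a group-B value.
#'
#' @param a,b Point matrices (or numeric vectors), one row per point.
#' @return List with `U`, `p_value` and the projection axis (or `NULL`).
#' @export
rank_sum_separation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stopf("both groups must be non-empty")
  axis <- NULL
  if (ncol(a) > 1) {
    axis <- robust_center(b) - robust_center(a)
    nrm <- sqrt(sum(axis^2))
    if (nrm > 0) axis <- axis / nrm
    va <- as.numeric(a %*% axis)
    vb <- as.numeric(b %*% axis)
  } else {
    va <- as.numeric(a); vb <- as.numeric(b)
  }
  if (length(unique(c(va, vb))) == 1) {
    warning("all projected values tied; p = 1")
    return(list(U = length(va) * length(vb) / 2, p_value = 1, axis = axis))
  }
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value, axis = axis)
}
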