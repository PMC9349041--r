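#' Create a vector-quantization codebook
#'
#' A codebook is a finite set of learnable code vectors shared across
#' spatial positions. Codes are updated during training either by an
#' exponential moving average over assigned latent vectors (default) or by
#' gradient descent on the codebook loss.
#'
#' @param n_codes Number of codes.
#' @param code_dim Code dimensionality.
#' @param update `"ema"` or `"gradient"`.
#' @param decay EMA decay (used when `update = "ema"`).
#' @param seed Seed for the initial code values.
#' @return Object of class `codebook`: list with `codes`
#'   (`n_codes x code_dim`), EMA accumulators, and settings.
#' @export
codebook <- function(n_codes, code_dim, update = c("ema", "gradient"),
                     decay = 0.99, seed = 1L) {
  update <- match.arg(update)
  codes <- with_seed(seed, matrix(stats::rnorm(n_codes * code_dim, sd = 0.5),
                                  n_codes, code_dim))
  structure(list(codes = codes,
                 ema_count = rep(1, n_codes),
                 ema_sum = codes,   # consistent with ema_count = 1
                 update = update, decay = decay,
                 n_codes = as.integer(n_codes), code_dim = as.integer(code_dim)),
            class = "codebook")
}

#' Split vector quantization
#'
#' Splits each spatial position's channel vector into `n_splits` contiguous
#' subvectors of equal length and replaces each subvector by its nearest
#' codebook entry (Euclidean distance, ties broken toward the lowest code
#' index). With `n_splits = 1` this is standard vector quantization. Split
#' quantization multiplies the number of quantized vectors per
#' representation without changing the spatial pooling, which markedly
#' improves codebook use (perplexity) for coarse latents.
#'
#' @param latent Array `(H, W, C, N)` (a single position may be given as a
#'   plain numeric vector), with `C = n_splits * code_dim`.
#' @param cb A [codebook] (or a plain `n_codes x code_dim` matrix).
#' @param n_splits Number of channel splits.
#' @return Object of class `quantization_result`: `indices` array
#'   `(H, W, n_splits, N)` of 1-based code ids, `quantized` array shaped
#'   like `latent`, `codebook_loss` and `commitment_loss` (mean squared
#'   latent-to-code distances; they share the value and differ only in
#'   which side the gradient treats as constant), `counts` (assignments per
#'   code) and `vectors`/`assignments` used for EMA codebook updates.
#' @export
split_quantize <- function(latent, cb, n_splits = 1L) {
  codes <- if (inherits(cb, "codebook")) cb$codes else cb
  if (is.null(dim(latent))) latent <- array(latent, c(1, 1, length(latent), 1))
  d <- dim(latent)
  if (length(d) == 3) { latent <- array(latent, c(d, 1)); d <- dim(latent) }
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  K <- nrow(codes); cd <- ncol(codes)
  if (C %% n_splits != 0) {
    stopf("channel count %d not divisible by n_splits = %d", C, n_splits)
  }
  if (C / n_splits != cd) {
    stopf("subvector length %d does not match code dimension %d", C / n_splits, cd)
  }
  ## rows of B are channel vectors, one per (position, image)
  B <- matrix(aperm(latent, c(1, 2, 4, 3)), H * W * N, C)
  half_nrm <- 0.5 * rowSums(codes * codes)
  Qb <- B
  idx <- matrix(0L, H * W * N, n_splits)
  for (s in seq_len(n_splits)) {
    cols <- ((s - 1) * cd + 1):(s * cd)
    score <- B[, cols, drop = FALSE] %*% t(codes)
    score <- sweep(score, 2, half_nrm)
    is_ <- max.col(score, ties.method = "first")
    idx[, s] <- is_
    Qb[, cols] <- codes[is_, , drop = FALSE]
  }
  quant <- aperm(array(Qb, c(H, W, N, C)), c(1, 2, 4, 3))
  msd <- mean((B - Qb)^2)
  indices <- aperm(array(idx, c(H, W, N, n_splits)), c(1, 2, 4, 3))
  structure(list(indices = indices, quantized = quant,
                 codebook_loss = msd, commitment_loss = msd,
                 counts = tabulate(idx, nbins = K),
                 vectors = B, assignments = idx,
                 n_splits = as.integer(n_splits)),
            class = "quantization_result")
}

#' @export
print.quantization_result <- function(x, ...) {
  d <- dim(x$quantized)
  cat(sprintf("<quantization_result> %d x %d map, %d split(s), commitment %.4g\n",
              d[1], d[2], x$n_splits, x$commitment_loss))
  invisible(x)
}

## EMA codebook update from a quantization result. Counts and sums decay at
## the same rate, so a code with no recent assignments keeps its value
## exactly (dead codes stay in place rather than being re-seeded).
vq_ema_update <- function(cb, qr, eps = 1e-12) {
  stopifnot(inherits(cb, "codebook"))
  if (cb$update != "ema") return(cb)
  K <- cb$n_codes; cd <- cb$code_dim
  idx <- as.integer(qr$assignments)
  counts <- tabulate(idx, nbins = K)
  sums <- matrix(0, K, cd)
  for (s in seq_len(ncol(qr$assignments))) {
    cols <- ((s - 1) * cd + 1):(s * cd)
    sub <- qr$vectors[, cols, drop = FALSE]
    agg <- rowsum(sub, qr$assignments[, s])
    used <- as.integer(rownames(agg))
    sums[used, ] <- sums[used, , drop = FALSE] + agg
  }
  cb$ema_count <- cb$decay * cb$ema_count + (1 - cb$decay) * counts
  cb$ema_sum <- cb$decay * cb$ema_sum + (1 - cb$decay) * sums
  cb$codes <- cb$ema_sum / pmax(cb$ema_count, eps)
  cb
}

#' Codebook perplexity
#'
#' Exponential of the entropy of code-usage frequencies:
#' `exp(-sum(p_k log p_k))` with `p_k = count_k / sum(counts)`. Ranges from
#' 1 (a single code carries everything) to `n_codes` (uniform use); the
#' effective number of codes in use.
#'
#' @param counts Non-negative assignment counts, one per code.
#' @return Scalar perplexity.
#' @export
perplexity <- function(counts) {
  if (any(counts < 0)) stopf("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stopf("perplexity undefined for all-zero counts")
  p <- counts[counts > 0] / tot
  exp(-sum(p * log(p)))
}
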