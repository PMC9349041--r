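# Independent oracles: deliberately naive transliterations used to check the
# vectorised implementations.

## exhaustive nearest-neighbour quantization of one vector
oracle_nearest_code <- function(v, codes) {
  d2 <- apply(codes, 1, function(cc) sum((v - cc)^2))
  which(d2 == min(d2))[1]   # lowest index on ties
}

## split quantization of a (H, W, C, N) latent by explicit loops
oracle_split_quantize <- function(latent, codes, n_splits) {
  d <- dim(latent)
  cd <- d[3] / n_splits
  idx <- array(0L, c(d[1], d[2], n_splits, d[4]))
  quant <- array(0, d)
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- latent[i, j, , n]
    for (s in seq_len(n_splits)) {
      sub <- v[((s - 1) * cd + 1):(s * cd)]
      k <- oracle_nearest_code(sub, codes)
      idx[i, j, s, n] <- k
      quant[i, j, ((s - 1) * cd + 1):(s * cd), n] <- codes[k, ]
    }
  }
  list(indices = idx, quantized = quant,
       msd = mean((latent - quant)^2))
}

## step-by-step counter simulation of the plateau schedule
oracle_schedule <- function(losses, initial_lr = 4e-4, factor = 0.1,
                            lr_patience = 4, stop_patience = 12, tol = 1e-6) {
  lr <- initial_lr
  best <- Inf
  stall <- 0
  plateau <- 0
  decays <- integer(0)
  stopped <- FALSE
  for (e in seq_along(losses)) {
    improved <- losses[e] < best - tol
    if (improved) {
      best <- losses[e]
      stall <- 0
      plateau <- 0
    } else {
      stall <- stall + 1
      plateau <- plateau + 1
    }
    if (!improved && plateau == lr_patience) {
      lr <- lr * factor
      plateau <- 0
      decays <- c(decays, e)
    }
    if (stall > stop_patience) {
      stopped <- TRUE
      break
    }
  }
  list(lr = lr, stop = stopped, decay_epochs = decays)
}

## direct transliteration of the robust clustering score definition
oracle_gamma <- function(points, labels) {
  mu_star <- function(m) apply(as.matrix(m), 2, median)
  sigma_star <- function(m) {
    m <- as.matrix(m)
    1.4826 * median(sqrt(rowSums(sweep(m, 2, mu_star(m))^2)))
  }
  cls <- unique(labels)
  centers <- t(sapply(cls, function(cl) mu_star(points[labels == cl, , drop = FALSE])))
  withins <- sapply(cls, function(cl) sigma_star(points[labels == cl, , drop = FALSE]))
  sigma_star(centers) / median(withins)
}

## brute-force max-over-z then 2x2 block mean
oracle_project <- function(vol) {
  d <- dim(vol)
  proj <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) proj[i, j] <- max(vol[i, j, ])
  out <- matrix(0, d[1] / 2, d[2] / 2)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- mean(proj[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  out
}

## nearest-boundary-pixel search; boundary = foreground pixel with a
## 4-neighbour in the background (or vice versa)
oracle_signed_distance <- function(mask) {
  d <- dim(mask)
  fg <- mask > 0
  is_boundary <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    nb <- c(if (i > 1) fg[i - 1, j], if (i < d[1]) fg[i + 1, j],
            if (j > 1) fg[i, j - 1], if (j < d[2]) fg[i, j + 1])
    if (any(nb != fg[i, j])) is_boundary[i, j] <- TRUE
  }
  bnd <- which(is_boundary & !fg, arr.ind = TRUE)  # background side of the edge
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dist <- min(sqrt((bnd[, 1] - i)^2 + (bnd[, 2] - j)^2))
    out[i, j] <- if (fg[i, j]) dist else -dist
  }
  out
}

## Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
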