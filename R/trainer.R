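#' Training configuration
#'
#' @param initial_lr Initial Adam learning rate (default 4e-4).
#' @param lr_factor Multiplier applied to the learning rate on a plateau
#'   (default 0.1).
#' @param lr_patience Epochs without validation improvement before a decay
#'   (default 4; the plateau counter resets after each decay).
#' @param stop_patience Stop when the validation loss has not improved for
#'   more than this many consecutive epochs (default 12).
#' @param split_ratios Train/validation/test proportions (default 8:1:1).
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param stratify Split within each protein instead of across all crops.
#' @param augment Random 90-degree rotations and flips during training.
#' @param improvement_tol Minimum absolute decrease of the best validation
#'   loss that counts as an improvement.
#' @param seed Seed controlling the split, shuffling and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(initial_lr = 4e-4, lr_factor = 0.1,
                         lr_patience = 4L, stop_patience = 12L,
                         split_ratios = c(0.8, 0.1, 0.1),
                         batch_size = 64L, max_epochs = 100L,
                         stratify = FALSE, augment = TRUE,
                         improvement_tol = 1e-6, seed = 1L) {
  if (lr_factor <= 0 || lr_factor >= 1) stopf("lr_factor must be in (0, 1)")
  if (lr_patience < 1 || stop_patience < 1) stopf("patiences must be >= 1")
  if (abs(sum(split_ratios) - 1) > 1e-8) stopf("split_ratios must sum to 1")
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 split_ratios = split_ratios,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 stratify = isTRUE(stratify), augment = isTRUE(augment),
                 improvement_tol = improvement_tol, seed = as.integer(seed)),
            class = "train_config")
}

split_counts <- function(n, ratios) {
  k <- floor(n * ratios)
  k[1] <- k[1] + (n - sum(k))   # remainder goes to the training partition
  k
}

#' Partition crops into train/validation/test
#'
#' @param cropset A `crop_set` (or its size as a single integer).
#' @param ratios Train/val/test proportions.
#' @param seed Seed; the assignment is a pure function of `(n, ratios, seed)`.
#' @param stratify Split within each protein id (requires a `crop_set` with
#'   an index), so every protein appears in each non-empty partition.
#' @return Character vector (`"train"`, `"val"`, `"test"`), one per crop.
#' @export
split_dataset <- function(cropset, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          stratify = FALSE) {
  n <- if (is.numeric(cropset)) as.integer(cropset) else length(cropset$crops)
  if (n < 1) stopf("empty crop set")
  labels <- c("train", "val", "test")
  if (!stratify) {
    k <- split_counts(n, ratios)
    perm <- with_seed(seed, sample.int(n))
    out <- character(n)
    out[perm] <- rep(labels, times = k)
    return(out)
  }
  ids <- cropset$index$protein_id
  if (is.null(ids)) stopf("stratified split requires protein ids in the crop index")
  out <- character(n)
  for (pid in unique(ids)) {
    w <- which(ids == pid)
    k <- split_counts(length(w), ratios)
    perm <- with_seed(child_seed(seed, "strat", match(pid, unique(ids))),
                      sample(w))
    out[perm] <- rep(labels, times = k)
  }
  out
}

rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

#' Randomly rotate and flip a crop
#'
#' Applies a random 90-degree rotation count and horizontal/vertical flips
#' to both channels jointly. All transforms are pixel permutations, so
#' channel value ranges are exactly preserved.
#'
#' @param crop `h x w x c` array.
#' @param seed Seed determining the transform.
#' @return Transformed crop.
#' @export
augment_crop <- function(crop, seed = 1L) {
  draw <- with_seed(seed, list(rot = sample(0:3, 1),
                               fh = stats::runif(1) < 0.5,
                               fv = stats::runif(1) < 0.5))
  out <- crop
  for (ch in seq_len(dim(crop)[3])) {
    m <- crop[, , ch]
    if (draw$rot > 0) for (r in seq_len(draw$rot)) m <- rot90cw(m)
    if (draw$fh) m <- m[, ncol(m):1, drop = FALSE]
    if (draw$fv) m <- m[nrow(m):1, , drop = FALSE]
    out[, , ch] <- m
  }
  out
}

#' Plateau-driven learning-rate schedule
#'
#' Pure function of a validation-loss history: starting from `initial_lr`,
#' the learning rate is multiplied by `lr_factor` every time the best
#' validation loss has not improved for `lr_patience` consecutive epochs
#' (the plateau counter resets after a decay), and training stops when the
#' loss has not improved for more than `stop_patience` consecutive epochs.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param config A [train_config].
#' @return List with `lr` (learning rate for the next epoch), `stop`
#'   (logical), `decay_epochs` (epochs after which a decay fired) and
#'   `best` (best loss seen).
#' @export
schedule_step <- function(val_losses, config = train_config()) {
  if (length(val_losses) == 0) stopf("empty validation history")
  lr <- config$initial_lr
  best <- Inf
  stall <- 0L; plateau <- 0L
  decay_epochs <- integer(0)
  stop_flag <- FALSE
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - config$improvement_tol) {
      best <- val_losses[e]
      stall <- 0L; plateau <- 0L
    } else {
      stall <- stall + 1L
      plateau <- plateau + 1L
      if (plateau >= config$lr_patience) {
        lr <- lr * config$lr_factor
        plateau <- 0L
        decay_epochs <- c(decay_epochs, e)
      }
      if (stall > config$stop_patience) {
        stop_flag <- TRUE
        break
      }
    }
  }
  list(lr = lr, stop = stop_flag, decay_epochs = decay_epochs, best = best)
}

snapshot_model <- function(model) {
  keep <- setdiff(ls(model), c("adam"))
  stats::setNames(lapply(keep, function(k) model[[k]]), keep)
}

restore_model <- function(snapshot) {
  m <- new.env(parent = emptyenv())
  for (k in names(snapshot)) m[[k]] <- snapshot[[k]]
  m$adam <- adam_state()
  class(m) <- "cytovq_model"
  m
}

eval_loss <- function(model, cropset, idx, targets, batch_size) {
  tot <- 0; n <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    x <- crops_to_batch(cropset, b)
    out <- model_forward(model, x)
    lb <- total_loss(out, targets[b], model$config$loss_weights)
    tot <- tot + lb$total * length(b)
    n <- n + length(b)
  }
  tot / n
}

#' Train the quantized autoencoder
#'
#' Adam optimization of the total loss with per-epoch validation, the
#' plateau learning-rate schedule of [schedule_step], early stopping, and
#' random rotation/flip augmentation of training crops. The returned model
#' is the best-validation checkpoint.
#'
#' @param model A [build_model] result whose `n_classes` matches the number
#'   of distinct protein ids in `cropset`.
#' @param cropset A `crop_set` with `protein_id` in its index.
#' @param config A [train_config].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `history` (data frame:
#'   epoch, train_loss, val_loss, lr, global_perplexity, local_perplexity),
#'   `assignment` (the split), and `classes` (protein id level order).
#' @export
train_model <- function(model, cropset, config = train_config(),
                        verbose = FALSE) {
  classes <- sort(unique(cropset$index$protein_id))
  if (length(classes) != model$config$n_classes && model$config$use_id_task) {
    stopf("model expects %d classes but crops contain %d proteins",
          model$config$n_classes, length(classes))
  }
  targets <- match(cropset$index$protein_id, classes)
  assignment <- split_dataset(cropset, config$split_ratios,
                              seed = child_seed(config$seed, "split"),
                              stratify = config$stratify)
  tr <- which(assignment == "train")
  va <- which(assignment == "val")
  if (length(tr) == 0) stopf("empty training partition")
  if (length(va) == 0) va <- tr   # degenerate tiny runs validate on train

  lr <- config$initial_lr
  best <- Inf; stall <- 0L; plateau <- 0L
  best_snap <- snapshot_model(model)
  hist <- list()
  val_losses <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(child_seed(config$seed, "epoch", epoch), sample(tr))
    ep_loss <- 0; ep_n <- 0
    cnt_g <- NULL; cnt_l <- NULL
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      x <- crops_to_batch(cropset, b)
      if (config$augment) {
        for (j in seq_along(b)) {
          x[, , , j] <- augment_crop(x[, , , j, drop = TRUE],
                                     child_seed(config$seed, "aug", epoch, b[j]))
        }
      }
      st <- train_step(model, x, targets[b], lr)
      ep_loss <- ep_loss + st$losses$total * length(b)
      ep_n <- ep_n + length(b)
      if (!is.null(st$counts_global)) {
        cnt_g <- if (is.null(cnt_g)) st$counts_global else cnt_g + st$counts_global
        cnt_l <- if (is.null(cnt_l)) st$counts_local else cnt_l + st$counts_local
      }
    }
    vloss <- eval_loss(model, cropset, va, targets, config$batch_size)
    val_losses <- c(val_losses, vloss)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = vloss, lr = lr,
      global_perplexity = if (!is.null(cnt_g)) perplexity(cnt_g) else NA_real_,
      local_perplexity = if (!is.null(cnt_l)) perplexity(cnt_l) else NA_real_)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.2g", epoch,
                      ep_loss / ep_n, vloss, lr))
    }
    if (vloss < best - config$improvement_tol) {
      best <- vloss; stall <- 0L; plateau <- 0L
      best_snap <- snapshot_model(model)
    } else {
      stall <- stall + 1L; plateau <- plateau + 1L
      if (plateau >= config$lr_patience) {
        lr <- lr * config$lr_factor
        plateau <- 0L
      }
      if (stall > config$stop_patience) break
    }
  }
  out_model <- restore_model(best_snap)
  list(model = out_model, history = do.call(rbind, hist),
       assignment = assignment, classes = classes)
}
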