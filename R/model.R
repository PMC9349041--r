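#' Model configuration
#'
#' Describes the two-level quantized autoencoder: a fine "local" latent
#' (quantized by VQ1) and a coarse "global" latent (quantized by VQ2 with
#' split quantization), two reconstruction decoders, and two
#' protein-identification classifier heads. The `use_*` toggles express the
#' structural ablations (dropping the nuclear channel, the distance
#' transform, vector quantization, the identification pretext task, split
#' quantization, or the decoders).
#'
#' @param input_shape `c(h, w, channels)` of a crop; default `c(100, 100, 2)`.
#' @param n_classes Number of protein identifiers (>= 2).
#' @param n_codes Codes per codebook (default 2048).
#' @param code_dim Code dimensionality (default 64).
#' @param n_splits Channel splits for the global quantizer (default 9).
#' @param global_shape `c(h, w, channels)` of the global latent; default
#'   `c(4, 4, n_splits * code_dim)`.
#' @param local_shape `c(h, w, channels)` of the local latent; default
#'   spatial side = input side / 4 (two stride-2 stages), `code_dim`
#'   channels.
#' @param classifier_hidden Hidden units in each classifier head.
#' @param width Base channel width of the convolutional backbone.
#' @param use_nuclear_channel If `FALSE`, the model takes 1-channel input.
#' @param use_distance_transform If `FALSE`, channel 2 is expected to carry
#'   the raw nuclear image rather than its signed distance transform
#'   (a preprocessing-level ablation recorded in the config).
#' @param use_vq,use_split_quantization,use_id_task,use_decoder Structural
#'   toggles.
#' @param commitment Commitment coefficient (weight of the commitment loss).
#' @param ema_decay Codebook EMA decay.
#' @param codebook_update `"ema"` or `"gradient"`.
#' @param loss_weights Named weights for `recon1`, `recon2`, `vq1`, `vq2`,
#'   `ce1`, `ce2`; `vq*` default to `commitment`.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_shape = c(100L, 100L, 2L), n_classes = 10L,
                         n_codes = 2048L, code_dim = 64L, n_splits = 9L,
                         global_shape = NULL, local_shape = NULL,
                         classifier_hidden = 1000L, width = 32L,
                         use_nuclear_channel = TRUE,
                         use_distance_transform = TRUE,
                         use_vq = TRUE, use_split_quantization = TRUE,
                         use_id_task = TRUE, use_decoder = TRUE,
                         commitment = 0.25, ema_decay = 0.99,
                         codebook_update = c("ema", "gradient"),
                         loss_weights = NULL) {
  codebook_update <- match.arg(codebook_update)
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (!use_nuclear_channel) input_shape[3] <- 1L
  ceil_half <- function(h) (h - 1L) %/% 2L + 1L
  if (is.null(local_shape)) {
    local_shape <- c(ceil_half(ceil_half(input_shape[1])),
                     ceil_half(ceil_half(input_shape[2])), code_dim)
  }
  if (is.null(global_shape)) global_shape <- c(4L, 4L, n_splits * code_dim)
  if (local_shape[3] != code_dim) {
    stopf("local channel count (%d) must equal code_dim (%d)",
          local_shape[3], code_dim)
  }
  if (global_shape[3] != n_splits * code_dim) {
    stopf("global channel count (%d) must equal n_splits * code_dim (%d)",
          global_shape[3], n_splits * code_dim)
  }
  h <- local_shape[1]; n_down <- 0L
  while (h > global_shape[1]) { h <- ceil_half(h); n_down <- n_down + 1L }
  if (h != global_shape[1]) {
    stopf("global side %d not reachable from local side %d by stride-2 stages",
          global_shape[1], local_shape[1])
  }
  w <- if (is.null(loss_weights)) {
    c(recon1 = 1, recon2 = 1, vq1 = commitment, vq2 = commitment, ce1 = 1, ce2 = 1)
  } else loss_weights
  structure(list(
    input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
    n_codes = as.integer(n_codes), code_dim = as.integer(code_dim),
    n_splits = as.integer(n_splits),
    global_shape = as.integer(global_shape),
    local_shape = as.integer(local_shape),
    classifier_hidden = as.integer(classifier_hidden),
    width = as.integer(width), n_down = n_down,
    use_nuclear_channel = use_nuclear_channel,
    use_distance_transform = use_distance_transform,
    use_vq = use_vq, use_split_quantization = use_split_quantization,
    use_id_task = use_id_task, use_decoder = use_decoder,
    commitment = commitment, ema_decay = ema_decay,
    codebook_update = codebook_update, loss_weights = w
  ), class = "model_config")
}

#' Build the quantized autoencoder
#'
#' Instantiates the network described by a [model_config]: `encoder1` maps
#' the input crop to the local latent, `encoder2` distils it into the
#' global latent, `decoder2` (ending in the dimension-adapting `mselyr1`
#' stage) reconstructs encoder2's input from the quantized global latent,
#' and `decoder1` reconstructs the image from the quantized local latent
#' concatenated with the global representation resized to the local grid.
#' `fc1`/`fc2` are two-layer perceptron identification heads on the
#' quantized local/global representations.
#'
#' @param config A [model_config].
#' @param seed Seed for weight initialization.
#' @return Object of class `cytovq_model` (an environment).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  cin <- config$input_shape[3]
  d <- config$code_dim
  gch <- config$global_shape[3]
  wd <- config$width
  L <- config$local_shape[1]
  G <- config$global_shape[1]
  nd <- config$n_down
  sd_ <- function(i) child_seed(seed, "layer", i)

  m <- new.env(parent = emptyenv())
  m$config <- config
  m$enc1 <- list(
    layer_conv(cin, wd, stride = 2L, seed = sd_(1)), layer_relu(),
    layer_conv(wd, wd, stride = 2L, seed = sd_(2)), layer_relu(),
    layer_conv(wd, d, stride = 1L, seed = sd_(3))
  )
  ## geometric channel schedule local -> global
  chs <- round(d * (gch / d)^(seq_len(nd) / nd))
  enc2 <- list(); prev <- d
  for (i in seq_len(nd)) {
    enc2 <- c(enc2, list(layer_conv(prev, chs[i], stride = 2L, seed = sd_(10 + i)),
                         layer_relu()))
    prev <- chs[i]
  }
  enc2 <- c(enc2, list(layer_conv(prev, gch, stride = 1L, seed = sd_(20))))
  m$enc2 <- enc2

  if (config$use_decoder) {
    dchs <- rev(c(d, chs[-nd]))
    dec2 <- list(); prev <- gch; side <- G
    for (i in seq_len(nd)) {
      dec2 <- c(dec2, list(layer_resize(c(side, side), c(2 * side, 2 * side)),
                           layer_conv(prev, dchs[i], stride = 1L, seed = sd_(30 + i)),
                           layer_relu()))
      prev <- dchs[i]; side <- 2 * side
    }
    ## mselyr1: adapt decoder2's output to encoder2's input dimensions
    dec2 <- c(dec2, list(layer_resize(c(side, side), c(L, L)),
                         layer_conv(prev, d, stride = 1L, seed = sd_(40))))
    m$dec2 <- dec2

    m$dec1 <- list(
      layer_conv(d + gch, wd, stride = 1L, seed = sd_(50)), layer_relu(),
      layer_resize(c(L, L), c(2 * L, 2 * L)),
      layer_conv(wd, wd, stride = 1L, seed = sd_(51)), layer_relu(),
      layer_resize(c(2 * L, 2 * L), c(4 * L, 4 * L)),
      layer_conv(wd, wd, stride = 1L, seed = sd_(52)), layer_relu(),
      layer_conv(wd, cin, stride = 1L, seed = sd_(53))
    )
  }
  m$rs_g2l <- layer_resize(c(G, G), c(L, L))

  if (config$use_id_task) {
    m$fc1 <- mlp_init(prod(config$local_shape), config$classifier_hidden,
                      config$n_classes, sd_(60))
    m$fc2 <- mlp_init(prod(config$global_shape), config$classifier_hidden,
                      config$n_classes, sd_(62))
  }
  if (config$use_vq) {
    cb2_dim <- if (config$use_split_quantization) d else gch
    m$cb1 <- codebook(config$n_codes, d, update = config$codebook_update,
                      decay = config$ema_decay, seed = child_seed(seed, "cb1"))
    m$cb2 <- codebook(config$n_codes, cb2_dim, update = config$codebook_update,
                      decay = config$ema_decay, seed = child_seed(seed, "cb2"))
  }
  m$adam <- adam_state()
  class(m) <- "cytovq_model"
  m
}

#' @export
print.cytovq_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cytovq_model> input %s | local %s | global %s | ",
                     "%d codes x %d dims, %d split(s)\n"),
              paste(cfg$input_shape, collapse = "x"),
              paste(cfg$local_shape, collapse = "x"),
              paste(cfg$global_shape, collapse = "x"),
              cfg$n_codes, cfg$code_dim,
              if (cfg$use_split_quantization) cfg$n_splits else 1L))
  invisible(x)
}

vq2_splits <- function(config) if (config$use_split_quantization) config$n_splits else 1L

#' Run the model forward
#'
#' @param model A [build_model] result.
#' @param x Batch array `(h, w, channels, n)` matching the configured input
#'   shape (a single crop `(h, w, channels)` is promoted to a batch of 1).
#' @param train Keep layer caches for the backward pass.
#' @return Object of class `forward_outputs`: `reconstruction`,
#'   `intermediate_reconstruction`, `logits_local`, `logits_global`,
#'   `quant_local`, `quant_global` ([split_quantize] results, `NULL` when
#'   `use_vq = FALSE`), plus the pre-quantization latents `latent_local`
#'   and `latent_global` and the `input`.
#' @export
model_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (!all(dim(x)[1:3] == cfg$input_shape)) {
    stopf("input shape %s does not match configured %s",
          paste(dim(x)[1:3], collapse = "x"),
          paste(cfg$input_shape, collapse = "x"))
  }
  e1 <- seq_forward(model$enc1, x)
  z1 <- e1$out
  e2 <- seq_forward(model$enc2, z1)
  z2 <- e2$out

  if (cfg$use_vq) {
    qr1 <- split_quantize(z1, model$cb1, 1L)
    qr2 <- split_quantize(z2, model$cb2, vq2_splits(cfg))
    q1 <- qr1$quantized; q2 <- qr2$quantized
  } else {
    qr1 <- qr2 <- NULL
    q1 <- z1; q2 <- z2
  }

  logits1 <- logits2 <- NULL
  fc1_cache <- fc2_cache <- NULL
  if (cfg$use_id_task) {
    n <- dim(x)[4]
    f1 <- t(matrix(q1, prod(cfg$local_shape), n))
    f2 <- t(matrix(q2, prod(cfg$global_shape), n))
    fc1_cache <- mlp_forward(model$fc1, f1)
    fc2_cache <- mlp_forward(model$fc2, f2)
    logits1 <- fc1_cache$logits
    logits2 <- fc2_cache$logits
  }

  xhat <- z1hat <- NULL
  d1 <- d2 <- NULL; cat_in <- NULL
  if (cfg$use_decoder) {
    d2 <- seq_forward(model$dec2, q2)
    z1hat <- d2$out
    g_res <- resize_forward(model$rs_g2l, q2)
    dims <- dim(q1)
    cat_in <- array(0, c(dims[1], dims[2], cfg$code_dim + cfg$global_shape[3], dims[4]))
    cat_in[, , seq_len(cfg$code_dim), ] <- q1
    cat_in[, , cfg$code_dim + seq_len(cfg$global_shape[3]), ] <- g_res
    d1 <- seq_forward(model$dec1, cat_in)
    xhat <- d1$out
  }

  out <- list(reconstruction = xhat, intermediate_reconstruction = z1hat,
              logits_local = logits1, logits_global = logits2,
              quant_local = qr1, quant_global = qr2,
              latent_local = z1, latent_global = z2, input = x)
  if (train) {
    out$caches <- list(e1 = e1, e2 = e2, d1 = d1, d2 = d2,
                       fc1 = fc1_cache, fc2 = fc2_cache, cat_in = cat_in)
  }
  structure(out, class = "forward_outputs")
}

#' Compute the training loss bundle
#'
#' Reconstruction terms are mean squared errors (image and intermediate
#' autoencoder), classification terms are categorical cross entropies of
#' the local and global identification heads, and quantization terms are
#' the commitment losses of the two quantizers. `total` is the weighted sum
#' of the present terms; terms disabled by configuration are `NA` and
#' excluded.
#'
#' @param outputs A [model_forward] result.
#' @param targets Integer class ids in `1..n_classes` (one per batch item);
#'   may be `NULL` when the identification task is disabled.
#' @param weights Named term weights (defaults from the model config used
#'   to produce `outputs` must be passed by the caller; see
#'   [model_config]).
#' @return Object of class `loss_bundle` with fields `recon1`, `recon2`,
#'   `vq1`, `vq2`, `ce1`, `ce2`, `weights`, `total`.
#' @export
total_loss <- function(outputs, targets = NULL,
                       weights = c(recon1 = 1, recon2 = 1, vq1 = 0.25,
                                   vq2 = 0.25, ce1 = 1, ce2 = 1)) {
  terms <- c(recon1 = NA_real_, recon2 = NA_real_, vq1 = NA_real_,
             vq2 = NA_real_, ce1 = NA_real_, ce2 = NA_real_)
  if (!is.null(outputs$reconstruction)) {
    terms["recon1"] <- mean((outputs$reconstruction - outputs$input)^2)
    terms["recon2"] <- mean((outputs$intermediate_reconstruction -
                               outputs$latent_local)^2)
  }
  if (!is.null(outputs$quant_local)) {
    terms["vq1"] <- outputs$quant_local$commitment_loss
    terms["vq2"] <- outputs$quant_global$commitment_loss
  }
  if (!is.null(outputs$logits_local)) {
    if (is.null(targets)) stopf("targets required when the id task is active")
    n_cls <- ncol(outputs$logits_local)
    if (any(targets < 1 | targets > n_cls)) stopf("targets out of range 1..%d", n_cls)
    terms["ce1"] <- softmax_ce(outputs$logits_local, targets)$loss
    terms["ce2"] <- softmax_ce(outputs$logits_global, targets)$loss
  }
  present <- !is.na(terms)
  total <- sum(weights[names(terms)[present]] * terms[present])
  structure(list(recon1 = terms[["recon1"]], recon2 = terms[["recon2"]],
                 vq1 = terms[["vq1"]], vq2 = terms[["vq2"]],
                 ce1 = terms[["ce1"]], ce2 = terms[["ce2"]],
                 weights = weights, total = total),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("<loss_bundle> total %.5g (recon %.3g/%.3g vq %.3g/%.3g ce %.3g/%.3g)\n",
              x$total, x$recon1, x$recon2, x$vq1, x$vq2, x$ce1, x$ce2))
  invisible(x)
}

## one optimization step: forward, loss, manual backward, Adam update of the
## weights and EMA update of the codebooks. Returns the loss bundle plus
## per-codebook assignment counts for perplexity tracking.
train_step <- function(model, x, targets, lr) {
  cfg <- model$config
  w <- cfg$loss_weights
  out <- model_forward(model, x, train = TRUE)
  ca <- out$caches
  n <- dim(out$input)[4]
  z1 <- out$latent_local; z2 <- out$latent_global
  q1 <- if (cfg$use_vq) out$quant_local$quantized else z1
  q2 <- if (cfg$use_vq) out$quant_global$quantized else z2

  dq1 <- array(0, dim(q1))
  dq2 <- array(0, dim(q2))
  grads <- list()

  if (cfg$use_decoder) {
    dxhat <- w[["recon1"]] * 2 * (out$reconstruction - out$input) / length(out$input)
    bk1 <- seq_backward(model$dec1, ca$d1$caches, dxhat)
    grads$dec1 <- bk1$grads
    dcat <- bk1$dx
    dq1 <- dq1 + dcat[, , seq_len(cfg$code_dim), , drop = FALSE]
    dgres <- dcat[, , cfg$code_dim + seq_len(cfg$global_shape[3]), , drop = FALSE]
    dq2 <- dq2 + resize_backward(model$rs_g2l, q2, dgres)$dx

    dz1hat <- w[["recon2"]] * 2 * (out$intermediate_reconstruction - z1) /
      length(z1)
    bk2 <- seq_backward(model$dec2, ca$d2$caches, dz1hat)
    grads$dec2 <- bk2$grads
    dq2 <- dq2 + bk2$dx
  }

  losses <- total_loss(out, targets, w)
  if (cfg$use_id_task) {
    sm1 <- softmax_ce(out$logits_local, targets)
    sm2 <- softmax_ce(out$logits_global, targets)
    b1 <- mlp_backward(model$fc1, ca$fc1, w[["ce1"]] * sm1$dlogits)
    b2 <- mlp_backward(model$fc2, ca$fc2, w[["ce2"]] * sm2$dlogits)
    grads$fc1 <- b1$grads
    grads$fc2 <- b2$grads
    dq1 <- dq1 + array(t(b1$dx), dim(q1))
    dq2 <- dq2 + array(t(b2$dx), dim(q2))
  }

  ## straight-through estimator plus commitment gradient
  dz1 <- dq1
  dz2 <- dq2
  if (cfg$use_vq) {
    dz1 <- dz1 + w[["vq1"]] * 2 * (z1 - q1) / length(z1)
    dz2 <- dz2 + w[["vq2"]] * 2 * (z2 - q2) / length(z2)
  }
  bke2 <- seq_backward(model$enc2, ca$e2$caches, dz2)
  grads$enc2 <- bke2$grads
  dz1 <- dz1 + bke2$dx
  bke1 <- seq_backward(model$enc1, ca$e1$caches, dz1)
  grads$enc1 <- bke1$grads

  model$adam$t <- model$adam$t + 1L
  for (block in names(grads)) {
    g <- grads[[block]]
    if (block %in% c("fc1", "fc2")) {
      for (nm in names(g)) {
        key <- paste(block, nm, sep = ".")
        model[[block]][[nm]] <- adam_update(model$adam, key,
                                            model[[block]][[nm]], g[[nm]], lr)
      }
    } else {
      for (i in seq_along(g)) {
        if (is.null(g[[i]])) next
        for (nm in names(g[[i]])) {
          key <- paste(block, i, nm, sep = ".")
          model[[block]][[i]][[nm]] <- adam_update(model$adam, key,
                                                   model[[block]][[i]][[nm]],
                                                   g[[i]][[nm]], lr)
        }
      }
    }
  }
  if (cfg$use_vq && cfg$codebook_update == "ema") {
    model$cb1 <- vq_ema_update(model$cb1, out$quant_local)
    model$cb2 <- vq_ema_update(model$cb2, out$quant_global)
  }
  list(losses = losses,
       counts_local = if (cfg$use_vq) out$quant_local$counts else NULL,
       counts_global = if (cfg$use_vq) out$quant_global$counts else NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS snapshot of the weights and codebooks, with the
#' configuration additionally written to a human-readable JSON sidecar
#' (`<path>.json`) when jsonlite is available.
#'
#' @param model A `cytovq_model`.
#' @param path Checkpoint file path.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  keep <- setdiff(ls(model), "adam")
  snap <- stats::setNames(lapply(keep, function(k) model[[k]]), keep)
  saveRDS(snap, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- model$config
    jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  snap <- readRDS(path)
  m <- new.env(parent = emptyenv())
  for (k in names(snap)) m[[k]] <- snap[[k]]
  m$adam <- adam_state()
  class(m) <- "cytovq_model"
  m
}
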