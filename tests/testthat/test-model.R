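test_that("latent shape contracts hold for a small configuration", {
  cfg <- tiny_model_config()
  expect_identical(cfg$local_shape, c(16L, 16L, 16L))
  expect_identical(cfg$global_shape, c(4L, 4L, 64L))
  m <- build_model(cfg, seed = 1)
  x <- array(runif(64 * 64 * 2 * 2), c(64, 64, 2, 2))
  out <- model_forward(m, x)
  expect_identical(dim(out$latent_local), c(16L, 16L, 16L, 2L))
  expect_identical(dim(out$latent_global), c(4L, 4L, 64L, 2L))
  expect_identical(dim(out$quant_local$indices), c(16L, 16L, 1L, 2L))
  expect_identical(dim(out$quant_global$indices), c(4L, 4L, 4L, 2L))
  expect_true(all(out$quant_local$indices >= 1 & out$quant_local$indices <= 32))
  expect_identical(dim(out$reconstruction), dim(x))
  expect_identical(dim(out$intermediate_reconstruction), dim(out$latent_local))
  expect_identical(dim(out$logits_global), c(2L, 5L))
})

test_that("misconfigured shapes are rejected", {
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(n_classes = 3, global_shape = c(4, 4, 100)),
               "n_splits")
  expect_error(model_config(n_classes = 3, local_shape = c(25, 25, 32)),
               "code_dim")
})

test_that("ablation toggles change the structure as configured", {
  # no nuclear channel: 1-channel input runs end to end
  m1 <- build_model(tiny_model_config(use_nuclear_channel = FALSE), seed = 1)
  expect_identical(m1$config$input_shape[3], 1L)
  out1 <- model_forward(m1, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_identical(dim(out1$reconstruction), c(64L, 64L, 1L, 1L))

  # no VQ: latents pass through unquantized
  m2 <- build_model(tiny_model_config(use_vq = FALSE), seed = 1)
  expect_null(m2$cb1)
  out2 <- model_forward(m2, array(runif(64 * 64 * 2), c(64, 64, 2, 1)))
  expect_null(out2$quant_local)
  lb2 <- total_loss(out2, 1L, m2$config$loss_weights)
  expect_true(is.na(lb2$vq1))

  # no id task: logits absent, ce excluded from the total
  m3 <- build_model(tiny_model_config(use_id_task = FALSE), seed = 1)
  expect_null(m3$fc1)
  out3 <- model_forward(m3, array(runif(64 * 64 * 2), c(64, 64, 2, 1)))
  expect_null(out3$logits_local)
  lb3 <- total_loss(out3, NULL, m3$config$loss_weights)
  expect_true(is.na(lb3$ce1) && is.finite(lb3$total))

  # no decoder: reconstructions absent, recon excluded
  m4 <- build_model(tiny_model_config(use_decoder = FALSE), seed = 1)
  expect_null(m4$dec1)
  out4 <- model_forward(m4, array(runif(64 * 64 * 2), c(64, 64, 2, 1)))
  expect_null(out4$reconstruction)
  lb4 <- total_loss(out4, 1L, m4$config$loss_weights)
  expect_true(is.na(lb4$recon1) && is.finite(lb4$total))

  # no split quantization: one global codebook entry per position
  m5 <- build_model(tiny_model_config(use_split_quantization = FALSE), seed = 1)
  expect_identical(ncol(m5$cb2$codes), 64L)
  out5 <- model_forward(m5, array(runif(64 * 64 * 2), c(64, 64, 2, 1)))
  expect_identical(dim(out5$quant_global$indices)[3], 1L)
})

test_that("an untrained model yields finite non-negative losses", {
  m <- build_model(micro_model_config(), seed = 4)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  out <- model_forward(m, x)
  lb <- total_loss(out, c(1L, 2L, 3L), m$config$loss_weights)
  vals <- c(lb$recon1, lb$recon2, lb$vq1, lb$vq2, lb$ce1, lb$ce2, lb$total)
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
  # forward is deterministic in inference mode
  out2 <- model_forward(m, x)
  expect_equal(out$reconstruction, out2$reconstruction)
  expect_identical(out$quant_local$indices, out2$quant_local$indices)
})

test_that("loss terms reach their minima and respect linear weighting", {
  # uniform logits over C classes give cross entropy ln C
  fake <- structure(list(
    logits_local = matrix(0, 2, 4), logits_global = matrix(0, 2, 4)),
    class = "forward_outputs")
  lb <- total_loss(fake, c(1L, 2L))
  expect_equal(lb$ce1, log(4))
  expect_equal(lb$ce2, log(4))

  # perfect reconstruction and one-hot-correct logits
  x <- array(runif(8), c(2, 2, 2, 1))
  z <- array(runif(4), c(1, 1, 4, 1))
  hot <- matrix(c(100, 0, 0, 0), 1, 4)
  perfect <- structure(list(reconstruction = x, input = x,
                            intermediate_reconstruction = z, latent_local = z,
                            logits_local = hot, logits_global = hot),
                       class = "forward_outputs")
  lb0 <- total_loss(perfect, 1L)
  expect_equal(lb0$recon1, 0)
  expect_equal(lb0$ce1, 0, tolerance = 1e-12)

  # doubling a weight doubles that term's contribution
  w <- c(recon1 = 1, recon2 = 1, vq1 = 0.25, vq2 = 0.25, ce1 = 1, ce2 = 1)
  w2 <- w; w2["ce1"] <- 2
  l1 <- total_loss(fake, c(1L, 2L), w)
  l2 <- total_loss(fake, c(1L, 2L), w2)
  expect_equal(l2$total - l1$total, l1$ce1)

  expect_error(total_loss(fake, c(1L, 9L)), "out of range")
})

test_that("backward passes match numerical gradients", {
  eps <- 1e-5
  # convolution, strided and padded
  l <- cytovq:::layer_conv(3, 4, kernel = 3, stride = 2, pad = 1, seed = 5)
  x <- array(rnorm(7 * 7 * 3 * 2), c(7, 7, 3, 2))
  out <- cytovq:::conv_forward(l, x)
  bk <- cytovq:::conv_backward(l, x, out)       # dL/dy = y for L = sum(y^2)/2
  f <- function(xx) sum(cytovq:::conv_forward(l, xx)^2) / 2
  withr::with_seed(1, idx <- sample(length(x), 20))
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bk$dx[i], (f(xp) - f(xm)) / (2 * eps), tolerance = 1e-5)
  }
  fW <- function(W) { l2 <- l; l2$W <- W; sum(cytovq:::conv_forward(l2, x)^2) / 2 }
  withr::with_seed(2, idxw <- sample(length(l$W), 20))
  for (i in idxw) {
    Wp <- l$W; Wp[i] <- Wp[i] + eps
    Wm <- l$W; Wm[i] <- Wm[i] - eps
    expect_equal(bk$grads$W[i], (fW(Wp) - fW(Wm)) / (2 * eps), tolerance = 1e-5)
  }

  # nearest-neighbour resize
  rl <- cytovq:::layer_resize(c(4, 4), c(7, 7))
  xr <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  outr <- cytovq:::resize_forward(rl, xr)
  bkr <- cytovq:::resize_backward(rl, xr, outr)
  fr <- function(xx) sum(cytovq:::resize_forward(rl, xx)^2) / 2
  for (i in seq_along(xr)) {
    xp <- xr; xp[i] <- xp[i] + eps
    xm <- xr; xm[i] <- xm[i] - eps
    expect_equal(bkr$dx[i], (fr(xp) - fr(xm)) / (2 * eps), tolerance = 1e-5)
  }

  # classifier head under cross entropy
  fc <- cytovq:::mlp_init(6, 5, 3, seed = 2)
  xm2 <- matrix(rnorm(12), 2, 6)
  tg <- c(1L, 3L)
  ca <- cytovq:::mlp_forward(fc, xm2)
  sm <- cytovq:::softmax_ce(ca$logits, tg)
  bkm <- cytovq:::mlp_backward(fc, ca, sm$dlogits)
  fm <- function(xx) cytovq:::softmax_ce(cytovq:::mlp_forward(fc, xx)$logits, tg)$loss
  for (i in seq_along(xm2)) {
    xp <- xm2; xp[i] <- xp[i] + eps
    xm_ <- xm2; xm_[i] <- xm_[i] - eps
    expect_equal(bkm$dx[i], (fm(xp) - fm(xm_)) / (2 * eps), tolerance = 1e-6)
  }
})

test_that("model checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  m <- build_model(micro_model_config(), seed = 9)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  out1 <- model_forward(m, x)
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  out2 <- model_forward(m2, x)
  expect_equal(out1$reconstruction, out2$reconstruction)
  expect_identical(out1$quant_global$indices, out2$quant_global$indices)
})
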