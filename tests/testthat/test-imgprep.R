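test_that("projection takes the z maximum before 2x2 block-mean downsampling", {
  vol <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(project_and_downsample(vol), oracle_project(vol), tolerance = 1e-12)

  const <- array(0.7, c(6, 6, 4))
  expect_true(all(project_and_downsample(const) == 0.7))

  expect_error(project_and_downsample(array(1, c(5, 6, 2))), "even")
})

test_that("a full-size confocal stack reduces to a half-side field of view", {
  vol <- array(runif(1024 * 1024 * 4), c(1024, 1024, 4))
  expect_identical(dim(project_and_downsample(vol)), c(512L, 512L))
})

test_that("Li threshold lands between the modes of a bimodal image", {
  img <- matrix(c(rnorm(600, 0.1, 0.02), rnorm(400, 0.9, 0.02)), 40, 25)
  thr <- threshold_li(img)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.85)
  # and classifies the two modes correctly
  expect_true(all(img[img > thr] > 0.5))
})

test_that("well-separated nuclei are segmented at high IoU", {
  sc <- render_scene("NUCLEAR_DIFFUSE", 4, 512, seed = 2)
  nu <- apply_noise(sc$nuclear, 200, 0.01, seed = 9)
  mask <- segment_nuclei(nu)
  expect_identical(max(mask), 4L)
  expect_true(all(recovery_ious(mask, sc$truth) >= 0.9))
})

test_that("an all-zero image yields an empty mask", {
  expect_identical(max(segment_nuclei(matrix(0, 128, 128))), 0L)
})

test_that("the LoG refinement splits nuclei merged by plain thresholding", {
  sc <- touching_nuclei_scene(gap = 8)
  lowpass <- as.matrix(EBImage::gblur(sc$nuclear, 10))
  plain <- EBImage::bwlabel((lowpass > threshold_li(lowpass)) * 1)
  expect_identical(max(plain), 1L)          # under-segmented without refinement
  refined <- segment_nuclei(sc$nuclear)
  expect_identical(max(refined), 2L)
  expect_true(all(recovery_ious(refined, sc$truth) >= 0.9))
})

test_that("closing radius below 4 px is rejected", {
  expect_error(segmentation_params(closing_radius = 2), "closing_radius")
})

test_that("signed distance matches a brute-force boundary search", {
  mask <- matrix(0L, 41, 41)
  mask[cytovq:::ellipse_mask(41, 21, 21, 10, 10, 0)] <- 1L
  dm <- signed_nuclear_distance(mask)
  oracle <- oracle_signed_distance(mask)
  # center value equals the disc radius up to discretisation
  expect_equal(dm$values[21, 21] * dm$scale_inside, 10, tolerance = 1.1)
  raw <- ifelse(dm$values >= 0, dm$values * dm$scale_inside,
                dm$values * dm$scale_outside)
  expect_equal(raw, oracle, tolerance = 1.5)
  # sign pattern matches mask membership away from the boundary
  interior <- abs(oracle) > 1.5
  expect_true(all(sign(dm$values[interior]) == sign(oracle[interior])))
  expect_equal(max(dm$values), 1)
  expect_true(all(dm$values >= -1 & dm$values <= 1))
})

test_that("an empty mask warns and returns a uniform negative map", {
  expect_warning(dm <- signed_nuclear_distance(matrix(0L, 16, 16)), "empty")
  expect_true(all(dm$values == -1))
})

test_that("crops are centered on nucleus centroids and skip the border", {
  mask <- matrix(0L, 512, 512)
  mask[cytovq:::ellipse_mask(512, 257, 257, 20, 20, 0)] <- 1L
  fl <- matrix(runif(512 * 512), 512, 512)
  dm <- signed_nuclear_distance(mask)
  cs <- extract_crops(fl, dm$values, mask, 100)
  expect_length(cs$crops, 1)
  expect_identical(cs$index$row_start, 207)
  expect_identical(cs$index$col_start, 207)
  expect_equal(cs$crops[[1]][, , 1], fl[207:306, 207:306])

  edge <- matrix(0L, 512, 512)
  edge[cytovq:::ellipse_mask(512, 10, 256, 8, 8, 0)] <- 1L
  cs2 <- extract_crops(fl, dm$values, edge, 100)
  expect_length(cs2$crops, 0)

  expect_error(extract_crops(fl, dm$values, mask, 600), "exceeds")
})

test_that("interior nuclei each produce one crop holding their centroid", {
  sc <- render_scene("NUCLEAR_DIFFUSE", 3, 512, seed = 6)
  mask <- segment_nuclei(sc$nuclear)
  dm <- signed_nuclear_distance(mask)
  cs <- extract_crops(sc$fluorescence, dm$values, mask, 100)
  interior <- sum(sapply(seq_len(max(mask)), function(k) {
    w <- which(mask == k, arr.ind = TRUE)
    cy <- round(mean(w[, 1])); cx <- round(mean(w[, 2]))
    cy - 50 >= 1 && cx - 50 >= 1 && cy + 49 <= 512 && cx + 49 <= 512
  }))
  expect_identical(length(cs$crops), interior)
  for (i in seq_along(cs$crops)) {
    ctr <- cs$crops[[i]][, , 2][51, 51]
    expect_gt(ctr, 0)   # centroid pixel sits inside its nucleus
  }
})

test_that("crop normalization is a min-max map and idempotent", {
  crop <- array(0, c(4, 4, 2))
  crop[, , 1] <- c(0, 5, 10, rep(5, 13))
  crop[, , 2] <- runif(16, -1, 1)
  nm <- normalize_crop(crop)
  expect_equal(sort(unique(as.numeric(nm[, , 1]))), c(0, 0.5, 1))
  expect_equal(normalize_crop(nm), nm)

  flat <- array(0.3, c(4, 4, 2))
  expect_warning(z <- normalize_crop(flat), "constant")
  expect_true(all(z[, , 1] == 0))
})

test_that("the full pipeline recovers most interior nuclei as valid crops", {
  cfg <- synth_config(n_proteins = 2, images_per_protein = 2, fov_size = 256,
                      nuclei_per_fov = c(3, 4),
                      family_of = c("NUCLEAR_DIFFUSE", "PUNCTATE"), seed = 17)
  ds <- generate_dataset(cfg)
  cs <- preprocess_dataset(ds, crop_size = 64)
  interior <- 0
  for (i in seq_along(ds$fovs)) {
    truth <- ds$nucleus_truth[[i]]
    for (k in seq_len(max(truth))) {
      w <- which(truth == k, arr.ind = TRUE)
      cy <- round(mean(w[, 1])); cx <- round(mean(w[, 2]))
      if (cy - 32 >= 1 && cx - 32 >= 1 && cy + 31 <= 256 && cx + 31 <= 256) {
        interior <- interior + 1
      }
    }
  }
  expect_gte(length(cs$crops) / interior, 0.9)
  # channel-range invariants hold for every crop
  for (cr in cs$crops) {
    expect_true(all(cr[, , 1] >= 0 & cr[, , 1] <= 1))
    expect_true(all(cr[, , 2] >= -1 & cr[, , 2] <= 1))
  }
})

test_that("crop sets round-trip through TIFF directories", {
  dir <- withr::local_tempdir()
  cs <- micro_cropset()
  write_crops(cs, dir)
  back <- read_crops(dir)
  expect_identical(length(back$crops), length(cs$crops))
  expect_identical(back$index$protein_id, cs$index$protein_id)
  # 16-bit storage: channels agree to quantisation precision
  expect_equal(back$crops[[1]], cs$crops[[1]], tolerance = 1e-4)
})
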