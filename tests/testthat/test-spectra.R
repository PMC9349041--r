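test_that("index histograms count codebook occurrences exactly", {
  m <- matrix(5L, 25, 25)
  h <- index_histogram(m, 8)
  expect_identical(h[5], 625L)
  expect_identical(sum(h), 625L)

  withr::with_seed(3, {
    maps <- list(matrix(sample(1:4, 9, TRUE), 3, 3),
                 matrix(sample(1:4, 9, TRUE), 3, 3))
    got <- index_histogram(maps, 4)
    want <- integer(4)
    for (mp in maps) for (v in as.integer(mp)) want[v] <- want[v] + 1L
    expect_identical(got, want)
    # additivity
    expect_identical(got, index_histogram(maps[1], 4) + index_histogram(maps[2], 4))
  })
  expect_error(index_histogram(matrix(9L, 2, 2), 4), "out of range")
})

test_that("spectrum matrices obey the counting identity", {
  withr::with_seed(6, {
    maps <- replicate(6, matrix(sample(1:10, 16, TRUE), 4, 4), simplify = FALSE)
    ids <- rep(c("P1", "P2", "P3"), each = 2)
    sm <- spectrum_matrix(maps, ids, 10)
    expect_identical(dim(sm), c(3L, 10L))
    expect_true(all(rowSums(sm) == 16 * 2))   # positions x images per protein
    smn <- spectrum_matrix(maps, ids, 10, normalize = TRUE)
    expect_equal(unname(rowSums(smn)), rep(1, 3))
  })
})

test_that("feature correlation is Pearson with the constant-column policy", {
  m <- cbind(c(1, 2, 3, 4), c(3, 7, 11, 15), c(4, 1, 2, 8), c(5, 5, 5, 5))
  cc <- feature_correlation(m)
  expect_equal(diag(cc), rep(1, 4))
  expect_equal(cc[1, 2], 1)                       # affine column
  expect_equal(cc[1, 3], oracle_pearson(m[, 1], m[, 3]))
  expect_equal(cc[2, 3], oracle_pearson(m[, 2], m[, 3]))
  expect_true(all(cc[4, -4] == 0))                # constant column
  expect_identical(cc, t(cc))
  expect_error(feature_correlation(m[1:2, ]), ">= 3")
})

test_that("biclustering orders correlated feature blocks contiguously", {
  expect_identical(bicluster_order(matrix(1, 1, 1))$order, 1L)

  # two perfectly correlated blocks, interleaved on purpose
  withr::with_seed(8, {
    n <- 12
    base1 <- rnorm(10); base2 <- rnorm(10)
    cols <- sapply(1:n, function(j) {
      if (j %% 2 == 0) base1 * runif(1, 0.5, 2) else base2 * runif(1, 0.5, 2)
    })
    cc <- feature_correlation(cols[1:10, ] + 0)
    ord <- bicluster_order(cc)
    expect_identical(sort(ord$order), 1:12)        # a permutation
    block <- (ord$order %% 2 == 0)
    expect_identical(length(rle(block)$lengths), 2L)  # each block contiguous
  })
  expect_error(bicluster_order(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("consensus prediction ranks the matching category first", {
  # query equal to one category's consensus, other categories uncorrelated
  mat <- rbind(A1 = c(10, 10, 0, 0, 1, 2), A2 = c(10, 10, 0, 0, 2, 1),
               B1 = c(0, 0, 10, 10, 1, 2), B2 = c(0, 0, 10, 10, 2, 1))
  ann <- annotation_table(organelle = data.frame(
    protein_id = c("A1", "A2", "B1", "B2"),
    organelle = c("nuc", "nuc", "cyt", "cyt")))
  pr <- consensus_and_predict(colMeans(mat[1:2, ]), mat, ann)
  expect_identical(pr$ranking$category[1], "nuc")
  expect_equal(pr$ranking$r[1], 1)

  # single category: always predicted
  ann1 <- annotation_table(organelle = data.frame(
    protein_id = c("A1", "A2"), organelle = "nuc"))
  pr1 <- suppressWarnings(consensus_and_predict(mat[3, ], mat[1:2, ], ann1))
  expect_identical(pr1$ranking$category, "nuc")

  # leave-out that empties a category warns and drops it
  ann2 <- annotation_table(organelle = data.frame(
    protein_id = c("A1", "B1"), organelle = c("nuc", "cyt")))
  expect_warning(pr2 <- consensus_and_predict(mat[1, ], mat, ann2, leave_out = "B1"),
                 "emptied")
  expect_false("cyt" %in% pr2$ranking$category)
})

test_that("leave-one-out prediction is highly accurate on family-coded spectra", {
  fx <- synth_family_spectra()
  res <- loo_prediction_accuracy(fx$matrix, fx$annotations, top_k = 1)
  expect_gte(res$accuracy, 0.9)
})

test_that("pairwise spectrum correlations separate families", {
  fx <- synth_family_spectra(n_per_family = 4)
  cc <- pairwise_spectrum_correlation(fx$matrix)
  expect_identical(cc, t(cc))
  expect_equal(diag(cc), rep(1, nrow(cc)), ignore_attr = TRUE)
  fam <- sub("_.*", "", rownames(fx$matrix))
  same <- cc[outer(fam, fam, "==") & upper.tri(cc)]
  diff_ <- cc[outer(fam, fam, "!=") & upper.tri(cc)]
  expect_gt(min(same), max(diff_))
  rs <- rank_sum_separation(same, diff_)
  expect_lt(rs$p_value, 1e-6)
})

test_that("nearest-neighbour complex fractions match brute force", {
  # two proteins, identical spectra, same complex
  m2 <- rbind(X = c(1, 2, 3, 4), Y = c(1, 2, 3, 4))
  annS <- annotation_table(complexes = data.frame(
    protein_id = c("X", "Y"), complex_id = "c1"))
  expect_equal(unname(neighbor_complex_fraction(m2, annS, 0.5)), 1)
  annD <- annotation_table(complexes = data.frame(
    protein_id = c("X", "Y"), complex_id = c("c1", "c2")))
  expect_equal(unname(neighbor_complex_fraction(m2, annD, 0.5)), 0)

  # impossible threshold reports NA, not zero
  expect_true(is.na(neighbor_complex_fraction(m2, annS, 1.5)))

  # 5-protein toy against exhaustive evaluation
  withr::with_seed(13, {
    base <- rnorm(12)
    mat <- rbind(P1 = base + rnorm(12, sd = 0.1),
                 P2 = base + rnorm(12, sd = 0.1),
                 P3 = rnorm(12), P4 = rnorm(12),
                 P5 = -base + rnorm(12, sd = 0.1))
    ann <- annotation_table(complexes = data.frame(
      protein_id = c("P1", "P2", "P3", "P4", "P5", "P5"),
      complex_id = c("a", "a", "b", "b", "a", "c")))
    ths <- c(-1, 0, 0.5, 0.9)
    got <- neighbor_complex_fraction(mat, ann, ths)
    cc <- suppressWarnings(pairwise_spectrum_correlation(mat))
    want <- sapply(ths, function(t) {
      hits <- c(); n <- 0
      for (i in 1:5) {
        rs <- cc[i, -i]
        j <- names(which.max(rs))
        if (max(rs) > t) {
          n <- n + 1
          ci <- ann$complexes$complex_id[ann$complexes$protein_id == rownames(mat)[i]]
          cj <- ann$complexes$complex_id[ann$complexes$protein_id == j]
          hits <- c(hits, length(intersect(ci, cj)) > 0)
        }
      }
      if (n == 0) NA_real_ else mean(hits)
    })
    expect_equal(unname(got), want)
  })
})
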