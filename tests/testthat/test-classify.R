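test_that("widely separated classes are classified almost perfectly", {
  sf <- separable_features(n = 64, p = 39, informative = 5, sep = 10,
                           seed = 4)
  res <- suppressWarnings(loo_classify(sf$X, sf$y))
  expect_gte(res$accuracy, 95)
  expect_equal(unname(rowSums(res$confusion)), c(100, 100),
               tolerance = 1e-9)
})

test_that("label permutation drops accuracy to chance", {
  sf <- separable_features(n = 64, p = 39, informative = 5, sep = 10,
                           seed = 4)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    suppressWarnings(loo_classify(sf$X, sample(sf$y))$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("fold normalization never sees the held-out sample", {
  sf <- separable_features(n = 20, p = 6, informative = 2, sep = 8,
                           seed = 2)
  X2 <- sf$X
  X2[3, ] <- X2[3, ] * 1e3          # permute/corrupt the held-out row
  # fold 3's training constants come from rows -3 only, so they are
  # unchanged by anything done to row 3
  nrm_a <- heartpp:::median_mad_normalizer(sf$X[-3, , drop = FALSE])
  nrm_b <- heartpp:::median_mad_normalizer(X2[-3, , drop = FALSE])
  expect_identical(nrm_a$apply(sf$X[1:2, ]), nrm_b$apply(sf$X[1:2, ]))
})

test_that("degenerate inputs are rejected or floored", {
  sf <- separable_features(n = 10, p = 3, informative = 2, seed = 5)
  expect_error(loo_classify(sf$X[sf$y == "a", ], sf$y[sf$y == "a"]),
               "two classes")
  Xc <- sf$X; Xc[, 2] <- 1
  expect_warning(loo_classify(Xc, sf$y), "zero training MAD")
})

test_that("classification is deterministic for a fixed table", {
  sf <- separable_features(n = 30, p = 10, informative = 3, sep = 3,
                           seed = 6)
  r1 <- suppressWarnings(loo_classify(sf$X, sf$y))
  r2 <- suppressWarnings(loo_classify(sf$X, sf$y))
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("RFE ranks planted informative features at the top", {
  sf <- separable_features(n = 40, p = 12, informative = 3, sep = 6,
                           seed = 8)
  rk <- suppressWarnings(svm_rfe_rank(sf$X, sf$y))
  expect_true(all(rank(rk$ranks, ties.method = "min")[1:3] <= 5))
  # every fold's ranking is a permutation of 1..p
  expect_true(all(apply(rk$rank_matrix, 1, sort) ==
                    seq_len(ncol(sf$X))))
})

test_that("single-feature RFE degenerates to the LOO accuracy point", {
  sf <- separable_features(n = 20, p = 1, informative = 1, sep = 8,
                           seed = 9)
  rk <- suppressWarnings(svm_rfe_rank(sf$X, sf$y))
  acc <- suppressWarnings(loo_classify(sf$X, sf$y))$accuracy
  expect_equal(rk$ranks, 1)
  expect_equal(rk$curve$accuracy, acc)
})

test_that("rank-accuracy curve is computed on the requested top-k sets", {
  sf <- separable_features(n = 24, p = 5, informative = 2, sep = 6,
                           seed = 10)
  rk <- suppressWarnings(svm_rfe_rank(sf$X, sf$y, curve = TRUE))
  expect_equal(rk$curve$k, 1:5)
  expect_true(all(rk$curve$accuracy >= 0 & rk$curve$accuracy <= 100))
})
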