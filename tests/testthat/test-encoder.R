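test_that("all-zero input gives exactly uniform attention and zero output", {
  X <- matrix(0, 3, 4)
  W <- matrix(rnorm(4 * 2), 4, 2)
  out <- self_attention(X, W, W, W)
  expect_equal(attr(out, "weights"), matrix(1 / 3, 3, 3))
  expect_equal(unclass(out), matrix(0, 3, 2), ignore_attr = TRUE)
})

test_that("the 2x2 identity example matches the closed-form softmax", {
  X <- diag(2)
  out <- self_attention(X, diag(2), diag(2), diag(2))
  z <- exp(1 / sqrt(2))
  w11 <- z / (z + 1)
  expect_equal(attr(out, "weights")[1, ], c(w11, 1 - w11))
  expect_equal(out[1, ], c(0.6698, 0.3302), tolerance = 1e-4)
  expect_equal(rowSums(attr(out, "weights")), c(1, 1), tolerance = 1e-12)
})

test_that("a single-token sequence passes its value row through unchanged", {
  X <- matrix(rnorm(5), 1, 5)
  Wv <- matrix(rnorm(15), 5, 3)
  out <- self_attention(X, matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3), Wv)
  expect_equal(attr(out, "weights"), matrix(1, 1, 1))
  expect_equal(unclass(out), X %*% Wv, ignore_attr = TRUE)
})

test_that("attention-weight rows sum to one on random inputs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      L <- sample(1:6, 1)
      d <- sample(2:6, 1)
      X <- matrix(rnorm(L * d, sd = 2), L, d)
      out <- self_attention(X, matrix(rnorm(d * 3), d, 3),
        matrix(rnorm(d * 3), d, 3), matrix(rnorm(d * 3), d, 3))
    })
    expect_equal(rowSums(attr(out, "weights")), rep(1, nrow(out)), tolerance = 1e-9)
  }
})

test_that("one head with identity output projection reduces to self-attention", {
  p <- attention_params(5, d_model = 6, heads = 1, seed = 2)
  p$Wo <- diag(6)
  X <- matrix(rnorm(18), 3, 6)
  got <- multi_head(X, p)
  ref <- self_attention(X, matrix(p$Wq[, , 1], 6, 6), matrix(p$Wk[, , 1], 6, 6),
    matrix(p$Wv[, , 1], 6, 6))
  expect_equal(got, unclass(ref), ignore_attr = TRUE)
})

test_that("two identical heads with an averaging output map equal one head", {
  withr::with_seed(5, {
    d <- 4; dk <- 2
    W1 <- matrix(rnorm(d * dk), d, dk)
    W2 <- matrix(rnorm(d * dk), d, dk)
    W3 <- matrix(rnorm(d * dk), d, dk)
    X <- matrix(rnorm(3 * d), 3, d)
  })
  two <- list(
    Wq = array(c(W1, W1), c(d, dk, 2)), Wk = array(c(W2, W2), c(d, dk, 2)),
    Wv = array(c(W3, W3), c(d, dk, 2)),
    Wo = rbind(0.5 * diag(dk), 0.5 * diag(dk))
  )
  one <- list(
    Wq = array(W1, c(d, dk, 1)), Wk = array(W2, c(d, dk, 1)),
    Wv = array(W3, c(d, dk, 1)), Wo = diag(dk)
  )
  expect_equal(multi_head(X, two), multi_head(X, one), tolerance = 1e-6)
})

test_that("multi_head matches the naive per-head reference on random instances", {
  for (seed in 1:20) {
    p <- attention_params(4, d_model = 8, heads = 4, seed = seed)
    X <- withr::with_seed(seed + 100, matrix(rnorm(5 * 8), 5, 8))
    expect_lt(max(abs(multi_head(X, p) - naive_multi_head(X, p$Wq, p$Wk, p$Wv, p$Wo))), 1e-6)
  }
})

test_that("head count must divide the model width", {
  expect_error(attention_params(10, d_model = 10, heads = 4), class = "tpmda_shape_error")
  p <- attention_params(4, d_model = 8, heads = 2)
  expect_error(multi_head(matrix(0, 2, 5), p), class = "tpmda_shape_error")
  expect_error(self_attention(matrix(0, 2, 3), diag(4), diag(4), diag(4)),
    class = "tpmda_shape_error")
})

test_that("a single one-node path with identity projections returns its embedding", {
  p <- attention_params(6, d_model = 4, heads = 1, seed = 9)
  p$Wq <- array(diag(4), c(4, 4, 1))
  p$Wk <- array(diag(4), c(4, 4, 1))
  p$Wv <- array(diag(4), c(4, 4, 1))
  p$Wo <- diag(4)
  expect_equal(encode_entity(list(3L), p), p$embed[3, ])
})

test_that("entity encoding is invariant to path duplication and order", {
  p <- attention_params(8, d_model = 8, heads = 2, seed = 1)
  paths <- list(c(1L, 5L, 2L), c(3L, 7L), c(4L, 6L, 8L))
  v <- encode_entity(paths, p)
  expect_equal(encode_entity(paths[c(2, 3, 1)], p), v)
  expect_equal(encode_entity(list(paths[[1]], paths[[1]]), p),
    encode_entity(list(paths[[1]]), p))
  # mean of per-path encodings, against the naive reference
  per_path <- sapply(paths, function(idx) {
    colMeans(naive_multi_head(p$embed[idx, , drop = FALSE], p$Wq, p$Wk, p$Wv, p$Wo))
  })
  expect_equal(v, rowMeans(per_path), tolerance = 1e-9)
  expect_error(encode_entity(list(), p), class = "tpmda_validation_error")
})

test_that("pair features concatenate in fixed (miRNA, disease) order", {
  expect_equal(pair_feature(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  v <- rnorm(5)
  expect_equal(pair_feature(v, numeric(5)), c(v, numeric(5)))
  expect_error(pair_feature(1:3, 1:4), class = "tpmda_shape_error")
  # injectivity over random draws
  withr::with_seed(8, {
    a <- matrix(rnorm(40), 10)
    b <- matrix(rnorm(40), 10)
  })
  feats <- apply(cbind(a, b), 1, function(r) paste(pair_feature(r[1:4], r[5:8]), collapse = ","))
  expect_equal(anyDuplicated(feats), 0)
})

test_that("matrix-flatten features are row ++ column with 0-based indexing", {
  R <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_equal(flatten_matrix_feature(R, 0, 0), c(1, 0, 1, 1))
  expect_equal(flatten_matrix_feature(R, 1, 1), c(1, 1, 0, 1))
  Z <- matrix(0, 2, 3)
  expect_equal(flatten_matrix_feature(Z, 0, 2), numeric(5))
  expect_error(flatten_matrix_feature(R, 2, 0), class = "tpmda_index_error")
})
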