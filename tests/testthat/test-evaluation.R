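test_that("folds partition positives and negatives are balanced and disjoint", {
  ds <- toy_dataset(n_mirna = 6, n_disease = 5, n_pairs = 10)
  fs <- make_folds(ds, k = 5, seed = 2)
  expect_length(fs$pos, 5)
  expect_true(all(vapply(fs$pos, nrow, integer(1)) == 2))
  expect_true(all(vapply(fs$neg, nrow, integer(1)) == 2))
  key <- function(df) paste(df$mirna_idx, df$disease_idx)
  all_pos <- unlist(lapply(fs$pos, key))
  expect_setequal(all_pos, key(ds$pairs))
  all_neg <- unlist(lapply(fs$neg, key))
  expect_equal(anyDuplicated(all_neg), 0) # pairwise disjoint
  expect_length(intersect(all_neg, key(ds$pairs)), 0) # disjoint from positives
  # reproducible
  fs2 <- make_folds(ds, k = 5, seed = 2)
  expect_equal(fs, fs2)
})

test_that("a dense matrix with too few unknowns raises a capacity error", {
  df <- tidyr::expand_grid(mirna = paste0("m", 1:3), disease = paste0("d", 1:3))
  ds <- association_dataset(df[-1, ]) # 8 positives, 1 unknown in a 3x3 grid
  expect_error(make_folds(ds, k = 5), "required", class = "tpmda_capacity_error")
})

test_that("fold sizes differ by at most one when positives do not divide k", {
  ds <- toy_dataset(n_mirna = 8, n_disease = 7, n_pairs = 13, seed = 9)
  fs <- make_folds(ds, k = 5, seed = 1)
  sizes <- vapply(fs$pos, nrow, integer(1))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 13)
  expect_equal(vapply(fs$neg, nrow, integer(1)), sizes)
})

test_that("confusion counts match the threshold rule and the naive oracle", {
  cts <- confusion(c(0.9, 0.2, 0.8, 0.4), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(cts), c(tp = 1, fn = 1, fp = 1, tn = 1))
  cts0 <- confusion(c(0.9, 0.2, 0.8, 0.4), c(1, 1, 0, 0), 0)
  expect_equal(cts0$fn + cts0$tn, 0)
  withr::with_seed(3, {
    s <- runif(200)
    y <- rbinom(200, 1, 0.4)
  })
  got <- confusion(s, y, 0.37)
  naive <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (i in seq_along(s)) {
    pred <- s[i] >= 0.37
    naive <- naive + c(pred & y[i] == 1, !pred & y[i] == 1, pred & y[i] == 0, !pred & y[i] == 0)
  }
  expect_equal(unlist(got), naive)
})

test_that("TPR/FPR and the two accuracy definitions follow their formulas", {
  c1 <- tibble::tibble(tp = 3, fn = 1, fp = 0, tn = 4)
  expect_equal(unlist(tpr_fpr(c1)), c(tpr = 0.75, fpr = 0))
  c2 <- tibble::tibble(tp = 1, fn = 3, fp = 2, tn = 2)
  expect_equal(unlist(tpr_fpr(c2)), c(tpr = 0.25, fpr = 0.5))
  expect_equal(validation_accuracy(tibble::tibble(tp = 9, fn = 1, fp = 5, tn = 0)), 0.9)
  expect_equal(validation_accuracy(tibble::tibble(tp = 0, fn = 4, fp = 0, tn = 1)), 0)
  expect_equal(overall_accuracy(c2), 3 / 8)
  expect_error(tpr_fpr(tibble::tibble(tp = 0, fn = 0, fp = 1, tn = 1)),
    class = "tpmda_undefined_rate_error")
  expect_error(validation_accuracy(tibble::tibble(tp = 0, fn = 0, fp = 1, tn = 1)),
    class = "tpmda_undefined_rate_error")
})

test_that("ROC endpoints, perfect separation, and the tie convention hold", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(r, "auc"), 1.0)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
  flat <- roc_auc(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(attr(flat, "auc"), 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), class = "tpmda_validation_error")
})

test_that("trapezoidal AUC equals the Mann-Whitney estimator", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      n <- sample(10:60, 1)
      s <- round(runif(n), digits = sample(c(1, 6), 1)) # force some ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    })
    r <- roc_auc(s, y)
    expect_equal(attr(r, "auc"), mw_auc(s, y), tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
  }
})

test_that("swapping labels maps AUC to its complement on tie-free scores", {
  withr::with_seed(12, {
    s <- sample(seq(0.01, 0.99, by = 0.01), 40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  })
  a <- attr(roc_auc(s, y), "auc")
  b <- attr(roc_auc(s, 1 - y), "auc")
  expect_equal(a + b, 1, tolerance = 1e-12)
})

test_that("label permutation centres the AUC at one half", {
  withr::with_seed(13, {
    s <- runif(300)
    y <- rbinom(300, 1, 0.5)
  })
  aucs <- vapply(1:20, function(i) {
    yp <- withr::with_seed(100 + i, sample(y))
    attr(roc_auc(s, yp), "auc")
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validation bookkeeping: one row per fold, validated on its own fold", {
  ds <- toy_dataset(n_mirna = 6, n_disease = 5, n_pairs = 10)
  cv <- cv_tpmda(ds, k = 5, seed = 3, mode = "tree", d_model = 4, heads = 2,
    max_depth = 2, max_paths = 4, max_len = 5,
    hidden_sizes = c(4, 4, 4), epochs = 3, learning_rate = 1e-3)
  tm <- tidy(cv)
  expect_equal(nrow(tm), 5)
  expect_equal(tm$fold, 1:5)
  expect_true(all(tm$n_val == 4)) # 2 positives + 2 negatives per fold
  expect_true(all(tm$n_train == 16))
  expect_equal(glance(cv)$cv_mse, mean(tm$mse))
})

test_that("planted-block cross-validation recovers held-out associations", {
  ds <- generate_associations(synthetic_spec(50, 40, 4, 0.7, 0.005, seed = 5))
  cv <- cv_tpmda(ds, k = 5, seed = 2, mode = "tree", d_model = 16, heads = 4,
    max_depth = 2, max_paths = 8, max_len = 7,
    hidden_sizes = c(64, 64, 32), epochs = 150, learning_rate = 1e-3)
  expect_gte(glance(cv)$mean_auc, 0.85)
  expect_true(all(tidy(cv)$mse < 0.5))
})

test_that("candidate ranking excludes known pairs and is deterministic", {
  ds <- generate_associations(synthetic_spec(20, 12, 2, 0.6, 0.02, seed = 8))
  train <- dplyr::bind_rows(
    dplyr::mutate(ds$pairs, label = 1L),
    dplyr::mutate(head(unknown_pairs(ds), n_pairs(ds)), label = 0L)
  )
  fit <- fit_tpmda(train, ds, mode = "tree", d_model = 8, heads = 2,
    max_depth = 2, max_paths = 4, max_len = 5,
    hidden_sizes = c(8, 8, 4), epochs = 5, learning_rate = 1e-3, seed = 4)
  disease <- ds$disease_names[1]
  top <- rank_candidates(fit, ds, disease, top_k = 15)
  known <- tidy(ds)$mirna[tidy(ds)$disease == disease]
  expect_length(intersect(top$mirna, known), 0)
  expect_equal(top$rank, seq_len(nrow(top)))
  expect_true(all(diff(top$score) <= 0))
  expect_lte(nrow(top), 15)
  # top_k larger than the candidate pool returns the whole pool
  all_cand <- rank_candidates(fit, ds, disease, top_k = 10000)
  expect_equal(nrow(all_cand), n_mirna(ds) - length(known))
  expect_equal(rank_candidates(fit, ds, disease, top_k = 15), top)
  expect_error(rank_candidates(fit, ds, "no such disease"), class = "tpmda_index_error")
})
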