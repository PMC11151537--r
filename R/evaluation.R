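# Experimental protocol: balanced fold-disjoint negative sampling, k-fold
# cross-validation, confusion/ROC metrics.

#' Balanced, fold-disjoint cross-validation folds
#'
#' Partitions the known positives into `k` near-equal folds and draws, for
#' each fold, an equal number of unknown (zero-cell) pairs as negatives.
#' Negative folds are pairwise disjoint and disjoint from the positive set,
#' so no negative sample is reused across fold experiments.
#'
#' @param x An `association_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the positive shuffle and negative
#'   draw.
#' @return A `fold_split` object: lists `pos` and `neg` of `k` tibbles of
#'   0-based `mirna_idx`, `disease_idx`.
#' @export
make_folds <- function(x, k = 5L, seed = 1L) {
  stopifnot(inherits(x, "association_dataset"), k >= 2L)
  P <- n_pairs(x)
  m <- n_mirna(x)
  n <- n_disease(x)
  n_unknown <- m * n - P
  required <- k * ceiling(P / k)
  if (n_unknown < required) {
    abort(sprintf(
      "insufficient unknown pairs for %d disjoint balanced negative folds: required %d, available %d",
      k, required, n_unknown
    ), class = "tpmda_capacity_error")
  }
  withr::with_seed(seed, {
    fold_of_pos <- sample(rep(seq_len(k), length.out = P))
    # rejection-free draw of P distinct unknown cells: sample linear cell
    # ids excluding the positives
    pos_lin <- x$pairs$mirna_idx * n + x$pairs$disease_idx # 0-based row-major
    neg_lin <- sample(setdiff(0:(m * n - 1L), pos_lin), P)
  })
  sizes <- tabulate(fold_of_pos, nbins = k)
  fold_of_neg <- rep(seq_len(k), times = sizes)
  pos_tbl <- tibble::tibble(
    mirna_idx = x$pairs$mirna_idx, disease_idx = x$pairs$disease_idx,
    fold = fold_of_pos
  )
  neg_tbl <- tibble::tibble(
    mirna_idx = neg_lin %/% n, disease_idx = neg_lin %% n,
    fold = fold_of_neg
  )
  structure(
    list(
      k = as.integer(k), seed = as.integer(seed),
      pos = lapply(seq_len(k), function(f) pos_tbl[pos_tbl$fold == f, 1:2]),
      neg = lapply(seq_len(k), function(f) neg_tbl[neg_tbl$fold == f, 1:2])
    ),
    class = "fold_split"
  )
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf(
    "<fold_split> k=%d; positive fold sizes: %s; balanced disjoint negatives\n",
    x$k, paste(vapply(x$pos, nrow, integer(1)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.fold_split <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(f) {
    dplyr::bind_rows(
      dplyr::mutate(x$pos[[f]], fold = f, label = 1L),
      dplyr::mutate(x$neg[[f]], fold = f, label = 0L)
    )
  })
}

#' Confusion counts at a score threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with integer `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length", class = "tpmda_shape_error")
  }
  pred <- scores >= threshold
  tibble::tibble(
    tp = sum(pred & labels == 1), fn = sum(!pred & labels == 1),
    fp = sum(pred & labels == 0), tn = sum(!pred & labels == 0)
  )
}

#' True- and false-positive rates
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`.
#'
#' @param counts A confusion-count row from [confusion()].
#' @return A one-row tibble with `tpr` and `fpr`.
#' @export
tpr_fpr <- function(counts) {
  if (counts$tp + counts$fn == 0 || counts$fp + counts$tn == 0) {
    abort("undefined rate: a class has zero evaluated samples",
      class = "tpmda_undefined_rate_error"
    )
  }
  tibble::tibble(
    tpr = counts$tp / (counts$tp + counts$fn),
    fpr = counts$fp / (counts$fp + counts$tn)
  )
}

#' Validation accuracy, as defined by the evaluation protocol
#'
#' `validation_accuracy()` returns `TP / (TP + FN)` — the protocol's printed
#' accuracy formula, which coincides with sensitivity/recall.
#' `overall_accuracy()` returns the conventional
#' `(TP + TN) / (TP + TN + FP + FN)`; both are reported side by side in
#' cross-validation output.
#'
#' @param counts A confusion-count row from [confusion()].
#' @return A single number in \[0, 1\].
#' @export
validation_accuracy <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    abort("undefined accuracy: no positive samples evaluated",
      class = "tpmda_undefined_rate_error"
    )
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname validation_accuracy
#' @export
overall_accuracy <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) {
    abort("undefined accuracy: no samples", class = "tpmda_undefined_rate_error")
  }
  (counts$tp + counts$tn) / tot
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (plus sentinels) and
#' returns the ROC polyline with its trapezoidal area. On tie-free scores the
#' trapezoidal AUC equals the Mann-Whitney estimator
#' `(#\{pos > neg\} + 0.5 #\{pos == neg\}) / (P * N)` exactly; score ties are
#' handled by the 0.5 convention (diagonal segments).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels; both classes must be present.
#' @return A `roc_curve` tibble (`threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1)) with the AUC in attribute `"auc"`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length", class = "tpmda_shape_error")
  }
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    abort("ROC requires both classes present", class = "tpmda_validation_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each unique-score cut (predict positive iff >= cut)
  last_of_tie <- c(diff(s) != 0, TRUE)
  cum_tp <- cumsum(y == 1)[last_of_tie]
  cum_fp <- cumsum(y == 0)[last_of_tie]
  curve <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, cum_fp / N),
    tpr = c(0, cum_tp / P)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(curve,
    class = c("roc_curve", class(tibble::tibble())),
    auc = auc, n_pos = P, n_neg = N
  )
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(
    auc = attr(x, "auc"), n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg")
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> AUC %.4f (%d positives, %d negatives, %d points)\n",
    attr(x, "auc"), attr(x, "n_pos"), attr(x, "n_neg"), nrow(x)
  ))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.4f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' k-fold cross-validated training and evaluation
#'
#' Runs the full protocol on a dataset: balanced fold-disjoint folds from
#' [make_folds()], then for each fold a model is trained from scratch (with a
#' fold-indexed seed) on the other folds' positives and negatives and scored
#' on the held-out fold's positives and its pre-assigned disjoint negatives.
#' Per fold it reports the trapezoidal AUC, the protocol accuracy
#' `TP/(TP+FN)` and conventional accuracy at `threshold`, and the mean
#' squared error of scores against 0/1 labels; the cross-validation summary
#' `CV(k)` is the mean of the fold MSEs.
#'
#' @param dataset An `association_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Master seed; fold f trains with `seed + f`.
#' @param threshold Classification threshold for the accuracy metrics.
#' @inheritParams fit_tpmda
#' @param ... Passed on to [fit_tpmda()] (e.g. `max_depth`, `max_paths`).
#' @return A `tpmda_cv` object; `tidy()` gives the per-fold metric tibble,
#'   `glance()` the CV summary.
#' @export
cv_tpmda <- function(dataset, k = 5L, seed = 1L, mode = c("tree", "matrix"),
                     threshold = 0.5, ...) {
  mode <- match.arg(mode)
  folds <- make_folds(dataset, k, seed)
  metrics <- purrr::map_dfr(seq_len(k), function(f) {
    train_pairs <- purrr::map_dfr(setdiff(seq_len(k), f), function(g) {
      dplyr::bind_rows(
        dplyr::mutate(folds$pos[[g]], label = 1L),
        dplyr::mutate(folds$neg[[g]], label = 0L)
      )
    })
    val_pairs <- dplyr::bind_rows(
      dplyr::mutate(folds$pos[[f]], label = 1L),
      dplyr::mutate(folds$neg[[f]], label = 0L)
    )
    fit <- fit_tpmda(train_pairs, dataset, mode = mode, seed = seed + f, ...)
    scored <- predict(fit, val_pairs)
    cts <- confusion(scored$.score, scored$label, threshold)
    tibble::tibble(
      fold = f,
      n_train = nrow(train_pairs), n_val = nrow(val_pairs),
      auc = attr(roc_auc(scored$.score, scored$label), "auc"),
      mse = mean((scored$.score - scored$label)^2),
      acc_validation = validation_accuracy(cts),
      acc_overall = overall_accuracy(cts),
      final_train_loss = glance(fit)$final_loss
    )
  })
  structure(
    list(metrics = metrics, k = as.integer(k), seed = as.integer(seed),
         mode = mode, cv_mse = mean(metrics$mse)),
    class = "tpmda_cv"
  )
}

#' @export
print.tpmda_cv <- function(x, ...) {
  cat(sprintf(
    "<tpmda_cv> %d-fold (%s mode): mean AUC %.4f, CV(k) MSE %.4f\n",
    x$k, x$mode, mean(x$metrics$auc), x$cv_mse
  ))
  invisible(x)
}

#' @export
tidy.tpmda_cv <- function(x, ...) x$metrics

#' @export
glance.tpmda_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, mode = x$mode, cv_mse = x$cv_mse,
    mean_auc = mean(x$metrics$auc),
    mean_acc_validation = mean(x$metrics$acc_validation),
    mean_acc_overall = mean(x$metrics$acc_overall)
  )
}

#' Per-fold metric plot for a cross-validation run
#'
#' @param object A `tpmda_cv`.
#' @param ... Unused.
#' @return A ggplot of AUC and accuracies by fold.
#' @export
autoplot.tpmda_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[, c("fold", "auc", "acc_validation", "acc_overall")],
    -"fold", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$fold), y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "fold", y = "value",
      title = sprintf("%d-fold cross-validation (%s mode)", object$k, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Rank candidate miRNAs for one disease
#'
#' Scores every unknown (miRNA, disease) pair for the given disease with a
#' trained model and returns the `top_k` highest-scoring candidates (ties
#' broken by miRNA name for determinism). Already-known associations never
#' appear in the output.
#'
#' @param fit A `tpmda_fit`.
#' @param dataset The `association_dataset` defining the known pairs.
#' @param disease Disease name.
#' @param top_k Number of candidates to return (default 15, the usual
#'   case-study list length).
#' @return A tibble with `rank`, `mirna`, `score`.
#' @export
rank_candidates <- function(fit, dataset, disease, top_k = 15L) {
  j <- match(disease, dataset$disease_names)
  if (is.na(j)) {
    abort(paste0("unknown disease name: ", disease), class = "tpmda_index_error")
  }
  known <- dataset$pairs$mirna_idx[dataset$pairs$disease_idx == j - 1L]
  cand <- setdiff(0:(n_mirna(dataset) - 1L), known)
  if (length(cand) == 0L) return(tibble::tibble(rank = integer(), mirna = character(), score = numeric()))
  scored <- predict(fit, tibble::tibble(mirna_idx = cand, disease_idx = j - 1L))
  scored |>
    dplyr::mutate(mirna = dataset$mirna_names[.data$mirna_idx + 1L]) |>
    dplyr::arrange(dplyr::desc(.data$.score), .data$mirna) |>
    head(top_k) |>
    dplyr::transmute(rank = dplyr::row_number(), mirna = .data$mirna, score = .data$.score)
}
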