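# End-to-end training: association matrix -> per-pair tree-paths ->
# attention encodings -> concatenated pair features -> FANN scores,
# with all parameters (embeddings, projections, classifier) updated
# jointly by full-batch Adam on binary cross-entropy.

# Per-entity path-sampling seed, derived deterministically from the run seed
# and the entity token; kept well below 2^31.
path_seed <- function(seed, token) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(token)) %% 2e9)
}

# Tree-mode unit construction. A "unit" is one side (miRNA or disease) of
# one candidate pair: its sampled tree-path token sequences. Pairs whose
# edge is absent from R share the plain per-entity unit; for known pairs the
# pair's own edge is removed from R before building either tree (leakage
# guard), giving the pair its own two units.
build_units_tree <- function(R, pairs, max_depth, max_paths, max_len, seed) {
  m <- nrow(R)
  units <- list()
  cache <- new.env(parent = emptyenv())
  add_unit <- function(paths) {
    units[[length(units) + 1L]] <<- paths
    length(units)
  }
  entity_unit <- function(Rm, kind, index) {
    tok <- token_id(kind, index, m)
    paths <- entity_path_tokens(
      Rm, kind, index, max_depth, max_paths, max_len,
      path_seed(seed, tok)
    )
    add_unit(paths)
  }
  cached_entity_unit <- function(kind, index) {
    key <- paste0(substr(kind, 1, 1), index)
    id <- cache[[key]]
    if (is.null(id)) {
      id <- entity_unit(R, kind, index)
      cache[[key]] <- id
    }
    id
  }
  B <- nrow(pairs)
  unit_m <- integer(B)
  unit_d <- integer(B)
  for (p in seq_len(B)) {
    i <- pairs$mirna_idx[p]
    j <- pairs$disease_idx[p]
    if (R[i + 1L, j + 1L] != 0) {
      Rp <- R
      Rp[i + 1L, j + 1L] <- 0L
      unit_m[p] <- entity_unit(Rp, "mirna", i)
      unit_d[p] <- entity_unit(Rp, "disease", j)
    } else {
      unit_m[p] <- cached_entity_unit("mirna", i)
      unit_d[p] <- cached_entity_unit("disease", j)
    }
  }
  list(units = units, unit_m = unit_m, unit_d = unit_d)
}

# Matrix-flatten mode: each pair's encoder input is row_i(R) ++ col_j(R)
# (own cell cleared), a length-(n + m) 0/1 token sequence fully described by
# its number of ones.
build_units_matrix <- function(R, pairs) {
  row_deg <- rowSums(R)
  col_deg <- colSums(R)
  own <- R[cbind(pairs$mirna_idx + 1L, pairs$disease_idx + 1L)]
  list(
    n_ones = row_deg[pairs$mirna_idx + 1L] + col_deg[pairs$disease_idx + 1L] - 2 * own,
    L = nrow(R) + ncol(R)
  )
}

# Flatten a list-of-units (each a list of token-id vectors) into the flat
# layout the C++ kernel consumes: stacked 0-based token rows, 0-based path
# start offsets, 0-based unit id per path, and paths-per-unit.
flatten_units <- function(units) {
  np <- lengths(units)
  all_paths <- unlist(units, recursive = FALSE, use.names = FALSE)
  lens <- lengths(all_paths)
  list(
    tokens0 = unlist(all_paths, use.names = FALSE) - 1L,
    starts0 = c(0L, cumsum(lens)),
    path_unit0 = rep(seq_along(units), times = np) - 1L,
    unit_np = as.numeric(np)
  )
}

encode_units_fwd <- function(theta, fl) {
  cpp_encode_paths(
    theta$E, fl$tokens0, fl$starts0, fl$path_unit0, fl$unit_np,
    theta$Wq, theta$Wk, theta$Wv, theta$Wo
  )
}

mlp_view <- function(theta, sizes) {
  structure(
    list(
      W1 = theta$W1, b1 = theta$b1, W2 = theta$W2, b2 = theta$b2,
      W3 = theta$W3, b3 = theta$b3, W4 = theta$W4, b4 = theta$b4,
      sizes = sizes
    ),
    class = "fann_model"
  )
}

#' Fit a tree-path attention association model
#'
#' Trains the full model end to end on a balanced table of labelled candidate
#' pairs: node embeddings and attention projections of the tree-path encoder
#' and the three-hidden-layer classifier are updated jointly by full-batch
#' Adam on binary cross-entropy. The association matrix used for tree
#' building contains the *training positives only*, and a training pair's own
#' edge is removed before its trees are built, so no pair can read its own
#' label from the structure it is encoded from.
#'
#' `mode = "matrix"` is the ablation baseline: the encoder input is the
#' flattened matrix row/column of the pair (see [flatten_matrix_feature()])
#' instead of tree-paths, lifted to model width by a learned linear map and
#' passed through the same attention encoder.
#'
#' @param train_pairs Data frame with 0-based `mirna_idx`, `disease_idx` and
#'   0/1 `label` columns.
#' @param dataset The `association_dataset` the indices refer to (supplies
#'   dimensions and names; its pair set is *not* consulted for tree
#'   building).
#' @param mode `"tree"` (tree-path encoder) or `"matrix"` (flatten ablation).
#' @param d_model Encoder width (default 64).
#' @param heads Attention heads (default 8); must divide `d_model`.
#' @param max_depth,max_paths,max_len Tree-path extraction controls, see
#'   [build_tree()] and [tree_paths()].
#' @param hidden_sizes Three hidden-layer widths (default `c(256, 256, 128)`).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param epochs Full-batch epochs (default 800).
#' @param seed Integer seed controlling initialisation and path sampling.
#' @return A `tpmda_fit` object; see [predict.tpmda_fit()],
#'   [tidy.tpmda_fit()], [glance.tpmda_fit()], [autoplot.tpmda_fit()].
#' @export
fit_tpmda <- function(train_pairs, dataset, mode = c("tree", "matrix"),
                      d_model = 64L, heads = 8L, max_depth = 4L,
                      max_paths = 64L, max_len = 7L,
                      hidden_sizes = c(256L, 256L, 128L),
                      learning_rate = 1e-5, epochs = 800L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(train_pairs),
            all(c("mirna_idx", "disease_idx", "label") %in% names(train_pairs)))
  train_pairs <- tibble::as_tibble(train_pairs)
  m <- n_mirna(dataset)
  n <- n_disease(dataset)
  y <- as.numeric(train_pairs$label)
  stopifnot(all(y %in% c(0, 1)), length(y) >= 2L)

  pos <- train_pairs[y == 1, c("mirna_idx", "disease_idx")]
  R_train <- matrix(0L, m, n)
  if (nrow(pos) > 0L) R_train[cbind(pos$mirna_idx + 1L, pos$disease_idx + 1L)] <- 1L

  cfg <- fann_config(hidden_sizes, learning_rate, epochs, seed)
  feat_len <- if (mode == "tree") 2L * d_model else d_model
  mlp <- fann_init(feat_len, cfg)
  sizes <- mlp$sizes
  enc <- attention_params(m + n, d_model, heads, seed)
  theta <- list(
    Wq = enc$Wq, Wk = enc$Wk, Wv = enc$Wv, Wo = enc$Wo,
    W1 = mlp$W1, b1 = mlp$b1, W2 = mlp$W2, b2 = mlp$b2,
    W3 = mlp$W3, b3 = mlp$b3, W4 = mlp$W4, b4 = mlp$b4
  )
  if (mode == "tree") {
    theta$E <- enc$embed
    wiring <- build_units_tree(R_train, train_pairs, max_depth, max_paths, max_len, seed)
    wiring$flat <- flatten_units(wiring$units)
  } else {
    withr::with_seed(seed, {
      theta$w <- rnorm(d_model, sd = 0.1)
      theta$b <- rnorm(d_model, sd = 0.1)
    })
    wiring <- build_units_matrix(R_train, train_pairs)
  }

  state <- adam_init(theta)
  B <- length(y)
  log <- tibble::tibble(epoch = seq_len(epochs), loss = NA_real_)
  for (epoch in seq_len(epochs)) {
    if (mode == "tree") {
      U <- encode_units_fwd(theta, wiring$flat)
      feats <- cbind(U[wiring$unit_m, , drop = FALSE], U[wiring$unit_d, , drop = FALSE])
    } else {
      U <- cpp_encode_binary_units(
        wiring$n_ones, wiring$L, theta$w, theta$b,
        theta$Wq, theta$Wk, theta$Wv, theta$Wo
      )
      feats <- U
    }
    model <- mlp_view(theta, sizes)
    cache <- fann_forward_cache(model, feats)
    log$loss[epoch] <- bce_loss(cache$scores, y)
    dZ4 <- (cache$scores - y) / B
    bk <- fann_backward(model, cache, dZ4)
    if (mode == "tree") {
      d <- d_model
      dHalf <- rbind(bk$dX[, 1:d, drop = FALSE], bk$dX[, d + 1:d, drop = FALSE])
      groups <- c(wiring$unit_m, wiring$unit_d)
      agg <- rowsum(dHalf, group = groups)
      dU <- matrix(0, length(wiring$units), d)
      dU[as.integer(rownames(agg)), ] <- agg
      eg <- cpp_encode_paths_grad(
        theta$E, wiring$flat$tokens0, wiring$flat$starts0,
        wiring$flat$path_unit0, wiring$flat$unit_np,
        theta$Wq, theta$Wk, theta$Wv, theta$Wo, dU
      )
      grads <- c(
        list(E = eg$dE, Wq = eg$dWq, Wk = eg$dWk, Wv = eg$dWv, Wo = eg$dWo),
        bk$grads
      )
    } else {
      eg <- cpp_encode_binary_units_grad(
        wiring$n_ones, wiring$L, theta$w, theta$b,
        theta$Wq, theta$Wk, theta$Wv, theta$Wo, bk$dX
      )
      grads <- c(
        list(
          w = as.numeric(eg$dw), b = as.numeric(eg$db),
          Wq = eg$dWq, Wk = eg$dWk, Wv = eg$dWv, Wo = eg$dWo
        ),
        bk$grads
      )
    }
    upd <- adam_step(theta, grads, state, learning_rate)
    theta <- upd$params
    state <- upd$state
  }

  structure(
    list(
      mode = mode, theta = theta, sizes = sizes,
      d_model = as.integer(d_model), heads = as.integer(heads),
      max_depth = as.integer(max_depth), max_paths = as.integer(max_paths),
      max_len = as.integer(max_len),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      seed = as.integer(seed),
      R_train = R_train,
      mirna_names = dataset$mirna_names, disease_names = dataset$disease_names,
      n_train = B, log = log
    ),
    class = "tpmda_fit"
  )
}

#' @export
print.tpmda_fit <- function(x, ...) {
  cat(sprintf(
    "<tpmda_fit> mode=%s d_model=%d heads=%d, %d training pairs, %d epochs, final loss %.4f\n",
    x$mode, x$d_model, x$heads, x$n_train, x$epochs, x$log$loss[x$epochs]
  ))
  invisible(x)
}

#' Score candidate miRNA-disease pairs
#'
#' Encodes each pair with the fitted encoder (trees built from the fit's
#' training positives, the pair's own edge removed if present) and returns
#' the classifier's association score in (0, 1).
#'
#' @param object A `tpmda_fit`.
#' @param pairs Data frame with 0-based `mirna_idx` and `disease_idx`.
#' @param ... Unused.
#' @return `pairs` as a tibble with a `.score` column appended.
#' @export
predict.tpmda_fit <- function(object, pairs, ...) {
  stopifnot(all(c("mirna_idx", "disease_idx") %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)
  theta <- object$theta
  if (object$mode == "tree") {
    wiring <- build_units_tree(
      object$R_train, pairs, object$max_depth, object$max_paths,
      object$max_len, object$seed
    )
    U <- encode_units_fwd(theta, flatten_units(wiring$units))
    feats <- cbind(U[wiring$unit_m, , drop = FALSE], U[wiring$unit_d, , drop = FALSE])
  } else {
    wiring <- build_units_matrix(object$R_train, pairs)
    feats <- cpp_encode_binary_units(
      wiring$n_ones, wiring$L, theta$w, theta$b,
      theta$Wq, theta$Wk, theta$Wv, theta$Wo
    )
  }
  scores <- fann_forward(mlp_view(theta, object$sizes), feats)
  dplyr::mutate(pairs, .score = scores)
}

#' Tidy the training log of a fit
#'
#' @param x A `tpmda_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss`.
#' @export
tidy.tpmda_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x A `tpmda_fit`.
#' @param ... Unused.
#' @return A tibble with the mode, dimensions and final training loss.
#' @export
glance.tpmda_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, d_model = x$d_model, heads = x$heads,
    n_train = x$n_train, epochs = x$epochs,
    learning_rate = x$learning_rate,
    final_loss = x$log$loss[x$epochs]
  )
}

#' Training-loss curve
#'
#' @param object A `tpmda_fit`.
#' @param ... Unused.
#' @return A ggplot of binary cross-entropy per epoch.
#' @export
autoplot.tpmda_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "epoch", y = "training cross-entropy",
      title = sprintf("tpmda training loss (%s mode)", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single archive holding the named parameter arrays
#' (embedding table, attention projections, classifier weights) plus the
#' configuration needed to rebuild the fit.
#'
#' @param fit A `tpmda_fit`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the `tpmda_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "tpmda_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "tpmda_fit"))
  fit
}
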