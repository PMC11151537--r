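# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Naive multi-head self-attention: explicit exponentials, one head at a time.
naive_multi_head <- function(X, Wq, Wk, Wv, Wo) {
  h <- dim(Wq)[3]
  d_k <- dim(Wq)[2]
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    Q <- X %*% matrix(Wq[, , i], ncol = d_k)
    K <- X %*% matrix(Wk[, , i], ncol = d_k)
    V <- X %*% matrix(Wv[, , i], ncol = d_k)
    S <- (Q %*% t(K)) / sqrt(d_k)
    A <- matrix(0, nrow(S), ncol(S))
    for (r in seq_len(nrow(S))) {
      e <- exp(S[r, ] - max(S[r, ]))
      A[r, ] <- e / sum(e)
    }
    outs[[i]] <- A %*% V
  }
  do.call(cbind, outs) %*% Wo
}

# Mann-Whitney AUC: pairwise comparison of every positive against every
# negative, ties counted half.
mw_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Breadth-first distances on the bipartite graph, via igraph. Vertices
# 1..m are miRNAs, m+1..m+n diseases.
igraph_bfs_oracle <- function(R, root_kind, root_index) {
  m <- nrow(R)
  n <- ncol(R)
  A <- rbind(
    cbind(matrix(0, m, m), R),
    cbind(t(R), matrix(0, n, n))
  )
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  root_v <- if (root_kind == "mirna") root_index + 1L else m + root_index + 1L
  as.numeric(igraph::distances(g, v = root_v))
}

# Random 0/1 matrix with at least one association.
random_assoc_matrix <- function(m, n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      R <- matrix(as.integer(runif(m * n) < p), m, n)
      if (sum(R) > 0) break
    }
    R
  })
}

# Tiny labelled dataset for protocol bookkeeping tests.
toy_dataset <- function(n_mirna = 6, n_disease = 5, n_pairs = 10, seed = 3) {
  withr::with_seed(seed, {
    cells <- sample(n_mirna * n_disease, n_pairs)
  })
  df <- tibble::tibble(
    mirna = sprintf("m%02d", (cells - 1) %/% n_disease + 1),
    disease = sprintf("d%02d", (cells - 1) %% n_disease + 1)
  )
  association_dataset(df)
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
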