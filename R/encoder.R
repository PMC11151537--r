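#' Initialise attention-encoder parameters
#'
#' Creates the learnable parameters of the tree-path encoder: one shared
#' embedding table with a row per entity (miRNAs first, then diseases, via
#' kind-offset indexing) and the per-head query/key/value projections plus
#' the output projection of multi-head self-attention. The head count must
#' divide the model width so that concatenating the `heads` head outputs
#' (each `d_model / heads` wide) maps back through `Wo` without padding.
#'
#' Embeddings are drawn N(0, 0.1); projections N(0, 1/sqrt(d_model)). All
#' draws are controlled by `seed`.
#'
#' @param n_entities Total number of entities (m miRNAs + n diseases).
#' @param d_model Embedding / model width (default 64).
#' @param heads Number of attention heads (default 8).
#' @param seed Integer seed for initialisation.
#' @return An `attention_params` list: `embed` (n_entities x d_model),
#'   `Wq`, `Wk`, `Wv` (d_model x d_k x heads arrays), `Wo`
#'   (heads*d_k x d_model), and the dimensions.
#' @export
attention_params <- function(n_entities, d_model = 64L, heads = 8L, seed = 1L) {
  stopifnot(n_entities >= 1L, d_model >= 1L, heads >= 1L)
  if (d_model %% heads != 0L) {
    abort(sprintf("d_model (%d) must be divisible by heads (%d)", d_model, heads),
      class = "tpmda_shape_error"
    )
  }
  d_k <- d_model %/% heads
  withr::with_seed(seed, {
    params <- list(
      embed = matrix(rnorm(n_entities * d_model, sd = 0.1), n_entities, d_model),
      Wq = array(rnorm(d_model * d_k * heads, sd = 1 / sqrt(d_model)), c(d_model, d_k, heads)),
      Wk = array(rnorm(d_model * d_k * heads, sd = 1 / sqrt(d_model)), c(d_model, d_k, heads)),
      Wv = array(rnorm(d_model * d_k * heads, sd = 1 / sqrt(d_model)), c(d_model, d_k, heads)),
      Wo = matrix(rnorm(heads * d_k * d_model, sd = 1 / sqrt(heads * d_k)), heads * d_k, d_model),
      d_model = as.integer(d_model), heads = as.integer(heads), d_k = as.integer(d_k)
    )
  })
  structure(params, class = "attention_params")
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Scaled dot-product self-attention
#'
#' One attention head: `softmax((X Wq)(X Wk)^T / sqrt(d_k)) (X Wv)`, with a
#' row-wise softmax, so each output position is a convex combination of the
#' value rows and every row of the attention-weight matrix sums to 1.
#'
#' @param X Sequence matrix, L x d_model (one row per token).
#' @param Wq,Wk,Wv Projection matrices, d_model x d_k.
#' @return The L x d_k output matrix, with the L x L attention-weight matrix
#'   attached as attribute `"weights"`.
#' @export
#' @examples
#' X <- diag(2)
#' out <- self_attention(X, diag(2), diag(2), diag(2))
#' rowSums(attr(out, "weights")) # both 1
self_attention <- function(X, Wq, Wk, Wv) {
  X <- as.matrix(X)
  check_dims <- function(W, nm) {
    if (nrow(W) != ncol(X)) {
      abort(sprintf("%s has %d rows but X has %d columns", nm, nrow(W), ncol(X)),
        class = "tpmda_shape_error"
      )
    }
  }
  check_dims(Wq, "Wq"); check_dims(Wk, "Wk"); check_dims(Wv, "Wv")
  if (ncol(Wq) != ncol(Wk)) {
    abort("Wq and Wk must share d_k", class = "tpmda_shape_error")
  }
  d_k <- ncol(Wq)
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  A <- row_softmax(Q %*% t(K) / sqrt(d_k))
  structure(A %*% V, weights = A)
}

#' Multi-head self-attention
#'
#' Runs `heads` scaled dot-product attention heads with separate projections,
#' concatenates their outputs and maps back to model width through the output
#' projection: `Concat(head_1, ..., head_h) Wo`.
#'
#' @param X Sequence matrix, L x d_model.
#' @param params An `attention_params` object (the embedding table is not
#'   used here), or any list with `Wq`, `Wk`, `Wv` (d_model x d_k x heads
#'   arrays) and `Wo`.
#' @return The L x d_model output matrix.
#' @export
multi_head <- function(X, params) {
  X <- as.matrix(X)
  Wq <- params$Wq; Wk <- params$Wk; Wv <- params$Wv; Wo <- params$Wo
  h <- dim(Wq)[3]
  d_k <- dim(Wq)[2]
  if (ncol(X) != dim(Wq)[1]) {
    abort(sprintf("X has %d columns but projections expect %d", ncol(X), dim(Wq)[1]),
      class = "tpmda_shape_error"
    )
  }
  pick <- function(W, i) matrix(W[, , i], dim(W)[1], dim(W)[2])
  heads <- lapply(seq_len(h), function(i) {
    out <- self_attention(X, pick(Wq, i), pick(Wk, i), pick(Wv, i))
    attr(out, "weights") <- NULL
    out
  })
  do.call(cbind, heads) %*% Wo
}

paths_to_tokens <- function(paths) {
  if (inherits(paths, "tree_paths")) {
    m <- attr(paths, "n_mirna")
    split(
      ifelse(paths$kind == "mirna", paths$index + 1L, m + paths$index + 1L),
      paths$path_id
    )
  } else if (is.list(paths)) {
    paths
  } else {
    abort("paths must be a tree_paths tibble or a list of token-id vectors",
      class = "tpmda_validation_error"
    )
  }
}

#' Encode one entity from its tree-paths
#'
#' Each tree-path is embedded (one embedding row per node), passed through
#' multi-head self-attention, and mean-pooled over its positions to give one
#' path vector; path vectors are then mean-pooled into a single d_model
#' entity encoding. Both pooling steps are order-invariant.
#'
#' @param paths A `tree_paths` tibble from [tree_paths()], or a list of
#'   1-based token-id integer vectors indexing `params$embed` rows.
#' @param params An `attention_params` object.
#' @param pooling Aggregation over paths; only `"mean"` is implemented.
#' @return A numeric vector of length `d_model`.
#' @export
encode_entity <- function(paths, params, pooling = "mean") {
  pooling <- match.arg(pooling, "mean")
  tokens <- paths_to_tokens(paths)
  if (length(tokens) == 0L) {
    abort("encode_entity requires at least one path", class = "tpmda_validation_error")
  }
  per_path <- vapply(tokens, function(idx) {
    X <- params$embed[idx, , drop = FALSE]
    colMeans(multi_head(X, params))
  }, numeric(params$d_model))
  rowMeans(matrix(per_path, nrow = params$d_model))
}

#' Concatenate the two entity encodings of a candidate pair
#'
#' @param vec_a miRNA-tree encoding (first half).
#' @param vec_b Disease-tree encoding (second half).
#' @return Numeric vector of length `2 * d_model`.
#' @export
pair_feature <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) {
    abort(sprintf(
      "pair_feature length mismatch: %d vs %d", length(vec_a), length(vec_b)
    ), class = "tpmda_shape_error")
  }
  c(vec_a, vec_b)
}

#' Flattened matrix-row/column feature (ablation mode)
#'
#' The association-matrix baseline input: the i-th row of R concatenated with
#' the j-th column, length n + m. In `mode = "matrix"` model fits this
#' sequence of 0/1 scalar tokens (lifted to d_model by a learned linear map)
#' replaces the tree-paths as encoder input.
#'
#' @param R Binary association matrix (m x n).
#' @param i,j 0-based miRNA and disease indices.
#' @return Numeric 0/1 vector of length `ncol(R) + nrow(R)`.
#' @export
flatten_matrix_feature <- function(R, i, j) {
  R <- as.matrix(R)
  if (i < 0L || i >= nrow(R) || j < 0L || j >= ncol(R)) {
    abort(sprintf("cell (%d, %d) out of range for %d x %d matrix", i, j, nrow(R), ncol(R)),
      class = "tpmda_index_error"
    )
  }
  c(as.numeric(R[i + 1L, ]), as.numeric(R[, j + 1L]))
}
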