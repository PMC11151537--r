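# Planted-block bipartite generator: recoverable ground truth for the whole
# pipeline without any external data. miRNA and disease sets are split into
# matched blocks; cells whose two blocks match associate with probability
# p_within, all other cells with p_between, independently per cell. The
# block model (rather than, say, degree-matched rewiring) is deliberate:
# the tree-path mechanism is expected to exploit transitive within-block
# structure, so planted blocks give a recovery signal the method should find.

#' Specification of a planted-block synthetic dataset
#'
#' @param n_mirna,n_disease Entity counts.
#' @param n_blocks Number of matched blocks; both entity sets are partitioned
#'   into `n_blocks` contiguous near-equal groups.
#' @param p_within Association probability when the miRNA and disease blocks
#'   match.
#' @param p_between Association probability otherwise; must satisfy
#'   `0 <= p_between < p_within <= 1`.
#' @param seed Integer seed; the realised dataset is a deterministic function
#'   of the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_mirna = 100L, n_disease = 80L, n_blocks = 4L,
                           p_within = 0.3, p_between = 0.005, seed = 1L) {
  stopifnot(n_mirna >= 1L, n_disease >= 1L, n_blocks >= 1L,
            n_blocks <= min(n_mirna, n_disease))
  if (!(p_between >= 0 && p_between < p_within && p_within <= 1)) {
    abort("require 0 <= p_between < p_within <= 1", class = "tpmda_validation_error")
  }
  structure(
    list(
      n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
      n_blocks = as.integer(n_blocks),
      p_within = p_within, p_between = p_between, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# near-even contiguous partition into n_blocks groups
block_assign <- function(n, n_blocks) {
  sizes <- rep(n %/% n_blocks, n_blocks) + (seq_len(n_blocks) <= n %% n_blocks)
  rep(seq_len(n_blocks), times = sizes)
}

#' Expected density of a planted-block spec
#'
#' Closed form: the block-matched cell fraction times `p_within` plus the
#' rest times `p_between`.
#'
#' @param spec A [synthetic_spec()].
#' @return Expected value of |pairs| / (m * n).
#' @export
expected_density <- function(spec) {
  bm <- block_assign(spec$n_mirna, spec$n_blocks)
  bd <- block_assign(spec$n_disease, spec$n_blocks)
  n_within <- sum(outer(bm, bd, `==`))
  total <- spec$n_mirna * spec$n_disease
  (n_within * spec$p_within + (total - n_within) * spec$p_between) / total
}

#' Generate a planted-block association dataset
#'
#' Draws every cell independently with its block-dependent probability.
#' Entities are named `m0001...` / `d0001...` and all entities are kept in
#' the dataset even if they drew no associations. If the realised matrix is
#' all-zero the draw is retried with an incremented sub-seed (up to 10
#' times).
#'
#' @param spec A [synthetic_spec()].
#' @return An `association_dataset` with the ground-truth block assignments
#'   attached as attribute `"blocks"` (list of `mirna_block`,
#'   `disease_block`) and the spec as attribute `"spec"`.
#' @export
generate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$n_mirna
  n <- spec$n_disease
  bm <- block_assign(m, spec$n_blocks)
  bd <- block_assign(n, spec$n_blocks)
  prob <- matrix(spec$p_between, m, n)
  prob[outer(bm, bd, `==`)] <- spec$p_within
  R <- NULL
  for (try in 0:9) {
    Rt <- withr::with_seed(spec$seed + try, {
      matrix(as.integer(runif(m * n) < prob), m, n)
    })
    if (sum(Rt) > 0L) {
      R <- Rt
      break
    }
  }
  if (is.null(R)) {
    abort("all-zero matrix realised 10 times; increase probabilities",
      class = "tpmda_validation_error"
    )
  }
  idx <- which(R == 1L, arr.ind = TRUE)
  mirna_names <- sprintf("m%04d", seq_len(m))
  disease_names <- sprintf("d%04d", seq_len(n))
  ds <- structure(
    list(
      mirna_names = mirna_names,
      disease_names = disease_names,
      pairs = tibble::tibble(
        mirna_idx = as.integer(idx[, 1] - 1L),
        disease_idx = as.integer(idx[, 2] - 1L)
      )
    ),
    class = "association_dataset"
  )
  attr(ds, "blocks") <- list(mirna_block = bm, disease_block = bd)
  attr(ds, "spec") <- spec
  ds
}

#' Planted holdout split with hard and easy negatives
#'
#' Removes a fraction of the *within-block* positives as test positives and
#' samples, per test positive, one unknown within-block cell (a "hard"
#' negative: the block signal says associate, the truth says no) and one
#' unknown between-block cell (an "easy" negative). The remaining positives
#' form the training positives, and an equal number of unknown cells —
#' disjoint from all positives and from both test negative sets — are drawn
#' as balanced training negatives. All six sets are mutually disjoint.
#'
#' @param dataset A dataset from [generate_associations()] (block attribute
#'   required).
#' @param fraction Fraction of within-block positives held out (default 0.2).
#' @param seed Integer seed for all draws.
#' @return A `planted_holdout` list of tibbles: `train_pairs` (balanced, with
#'   `label`), `test_pos`, `test_neg_hard`, `test_neg_easy`.
#' @export
holdout_planted <- function(dataset, fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "association_dataset"), fraction > 0, fraction < 1)
  blocks <- attr(dataset, "blocks")
  if (is.null(blocks)) {
    abort("dataset carries no block ground truth; use generate_associations()",
      class = "tpmda_validation_error"
    )
  }
  m <- n_mirna(dataset)
  n <- n_disease(dataset)
  pairs <- dataset$pairs
  within <- blocks$mirna_block[pairs$mirna_idx + 1L] ==
    blocks$disease_block[pairs$disease_idx + 1L]
  n_test <- round(fraction * sum(within))
  if (n_test < 1L || n_test >= nrow(pairs)) {
    abort("too few positives for the requested holdout fraction",
      class = "tpmda_capacity_error"
    )
  }
  pos_lin <- pairs$mirna_idx * n + pairs$disease_idx
  cell_within <- outer(blocks$mirna_block, blocks$disease_block, `==`)
  lin_all <- as.vector(t(cell_within)) # row-major: i * n + j order
  zero_lin <- setdiff(0:(m * n - 1L), pos_lin)
  zero_within <- zero_lin[lin_all[zero_lin + 1L]]
  zero_between <- zero_lin[!lin_all[zero_lin + 1L]]
  if (length(zero_within) < n_test || length(zero_between) < n_test) {
    abort("not enough unknown cells for balanced test negatives",
      class = "tpmda_capacity_error"
    )
  }
  withr::with_seed(seed, {
    test_pos_rows <- sample(which(within), n_test)
    hard_lin <- sample(zero_within, n_test)
    easy_lin <- sample(zero_between, n_test)
    remaining <- setdiff(zero_lin, c(hard_lin, easy_lin))
    n_train_pos <- nrow(pairs) - n_test
    train_neg_lin <- sample(remaining, min(n_train_pos, length(remaining)))
  })
  lin_tbl <- function(lin) {
    tibble::tibble(mirna_idx = lin %/% n, disease_idx = lin %% n)
  }
  train_pos <- pairs[-test_pos_rows, ]
  structure(
    list(
      train_pairs = dplyr::bind_rows(
        dplyr::mutate(train_pos, label = 1L),
        dplyr::mutate(lin_tbl(train_neg_lin), label = 0L)
      ),
      test_pos = pairs[test_pos_rows, ],
      test_neg_hard = lin_tbl(hard_lin),
      test_neg_easy = lin_tbl(easy_lin)
    ),
    class = "planted_holdout"
  )
}
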