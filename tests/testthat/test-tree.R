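toy_R <- matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))

test_that("the 2x2 toy matrix yields the chain m1 / d1 / m2 / d2", {
  tr <- build_tree(toy_R, root = "m1", root_kind = "mirna", max_depth = 4)
  expect_equal(tr$name, c("m1", "d1", "m2", "d2"))
  expect_equal(tr$depth, 0:3)
  expect_equal(tr$kind, c("mirna", "disease", "mirna", "disease"))
  p <- tree_paths(tr, max_paths = 10, max_len = 7)
  expect_equal(unique(p$path_id), 1L)
  expect_equal(p$name, c("m1", "d1", "m2", "d2"))
})

test_that("max_depth 0 gives a root-only tree and its single trivial path", {
  tr <- build_tree(toy_R, root = 0L, root_kind = "disease", max_depth = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$kind, "disease")
  p <- tree_paths(tr)
  expect_equal(nrow(p), 1)
  expect_equal(p$step, 1L)
})

test_that("an isolated root yields a root-only tree, out-of-range root errors", {
  R <- rbind(c(0, 0), c(1, 1))
  tr <- build_tree(R, root = 0L, root_kind = "mirna")
  expect_equal(nrow(tr), 1)
  expect_error(build_tree(R, root = 5L, root_kind = "mirna"), class = "tpmda_index_error")
  expect_error(build_tree(toy_R, root = "nope", root_kind = "disease"),
    class = "tpmda_index_error")
})

test_that("node set and depths match an independent graph-search oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    R <- random_assoc_matrix(8, 8, 0.18, seed = seed)
    root_kind <- if (seed %% 2 == 0) "mirna" else "disease"
    root_index <- seed %% 8
    tr <- build_tree(R, root_index, root_kind, max_depth = 100)
    dist <- igraph_bfs_oracle(R, root_kind, root_index)
    tok <- ifelse(tr$kind == "mirna", tr$index + 1, nrow(R) + tr$index + 1)
    # reachable set
    expect_setequal(tok, which(is.finite(dist)))
    # depth == shortest-path distance
    expect_equal(tr$depth, dist[tok])
    # it is a tree
    expect_equal(sum(!is.na(tr$parent)), nrow(tr) - 1)
    # alternating kinds by depth parity
    root_k <- tr$kind[1]
    expect_true(all((tr$kind == root_k) == (tr$depth %% 2 == 0)))
  }
})

test_that("depth capping intersects the component with the hop limit", {
  R <- random_assoc_matrix(8, 8, 0.2, seed = 7)
  dist <- igraph_bfs_oracle(R, "mirna", 0)
  for (cap in 0:3) {
    tr <- build_tree(R, 0L, "mirna", max_depth = cap)
    expect_equal(nrow(tr), sum(is.finite(dist) & dist <= cap))
    expect_lte(max(tr$depth), cap)
  }
})

test_that("every extracted path is a valid walk through 1-cells of R", {
  R <- random_assoc_matrix(8, 8, 0.25, seed = 13)
  tr <- build_tree(R, 2L, "mirna", max_depth = 4)
  p <- tree_paths(tr, max_paths = 200, max_len = 7)
  for (pid in unique(p$path_id)) {
    seg <- p[p$path_id == pid, ]
    expect_equal(seg$name[1], tr$name[1])
    for (s in seq_len(nrow(seg) - 1)) {
      a <- seg[s, ]
      b <- seg[s + 1, ]
      ij <- if (a$kind == "mirna") c(a$index, b$index) else c(b$index, a$index)
      expect_equal(R[ij[1] + 1, ij[2] + 1], 1)
    }
  }
})

test_that("all root-to-leaf paths are returned when the leaf count fits", {
  # star: one miRNA linked to 5 diseases
  R <- matrix(1, 1, 5)
  tr <- build_tree(R, 0L, "mirna")
  p <- tree_paths(tr, max_paths = 10)
  expect_equal(length(unique(p$path_id)), 5)
  expect_true(all(tapply(p$step, p$path_id, max) == 2))
})

test_that("leaf sampling is uniform without replacement and seed-reproducible", {
  R <- matrix(1, 1, 5)
  tr <- build_tree(R, 0L, "mirna")
  p1 <- tree_paths(tr, max_paths = 3, seed = 42)
  p2 <- tree_paths(tr, max_paths = 3, seed = 42)
  expect_equal(p1, p2)
  leaves <- p1$name[p1$step == 2]
  expect_equal(length(leaves), 3)
  expect_equal(anyDuplicated(leaves), 0)
  p3 <- tree_paths(tr, max_paths = 3, seed = 43)
  expect_equal(length(unique(p3$name[p3$step == 2])), 3)
})

test_that("paths are truncated at max_len nodes from the root", {
  tr <- build_tree(toy_R, root = "m1", root_kind = "mirna")
  p <- tree_paths(tr, max_len = 2)
  expect_equal(p$name, c("m1", "d1"))
})

test_that("a connected matrix explored without depth cap visits every entity", {
  R <- matrix(1, 4, 3)
  tr <- build_tree(R, 1L, "disease", max_depth = 1000)
  expect_equal(nrow(tr), 4 + 3)
})

test_that("the outline and path TSV exports are well-formed", {
  tr <- build_tree(toy_R, root = "m1", root_kind = "mirna")
  out <- format_tree_outline(tr)
  expect_length(out, 4)
  expect_match(out[1], "^0 mirna m1$")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_paths_tsv(tree_paths(tr), tf)
  expect_equal(readLines(tf), "m1\td1\tm2\td2")
})
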