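#' Build a per-entity association tree
#'
#' Grows the association tree rooted at one entity by breadth-first expansion
#' of the binary association matrix: the children of a miRNA node are all
#' diseases linked to it in R, and vice versa, so layers alternate between
#' the two entity kinds and depth-k nodes are exactly k association hops from
#' the root. Each entity enters the tree at most once, attached to its
#' earliest-discovered parent (ties broken by parent discovery order, then by
#' ascending child index), which makes node depth equal to the shortest-path
#' distance from the root in the bipartite association graph. Expansion stops
#' at `max_depth` or when the root's connected component is exhausted.
#'
#' @param x An `association_dataset` or a 0/1 matrix (rows = miRNAs,
#'   columns = diseases).
#' @param root Root entity: 0-based index within its kind, or an entity name
#'   when `x` carries names.
#' @param root_kind `"mirna"` or `"disease"`.
#' @param max_depth Maximum node depth (root has depth 0). Default 4: root,
#'   plus three alternating layers of indirect associations.
#' @return An `association_tree`: a tibble of nodes (`node_id`, `kind`,
#'   `index`, `name`, `depth`, `parent`) in breadth-first discovery order,
#'   with the root in row 1.
#' @export
#' @examples
#' R <- matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
#' build_tree(R, root = "m1", root_kind = "mirna")
build_tree <- function(x, root, root_kind = c("mirna", "disease"), max_depth = 4L) {
  root_kind <- match.arg(root_kind)
  R <- if (inherits(x, "association_dataset")) association_matrix(x) else as.matrix(x)
  stopifnot(max_depth >= 0)
  mirna_names <- rownames(R) %||% paste0("mirna_", seq_len(nrow(R)) - 1L)
  disease_names <- colnames(R) %||% paste0("disease_", seq_len(ncol(R)) - 1L)
  if (is.character(root)) {
    pool <- if (root_kind == "mirna") mirna_names else disease_names
    idx <- match(root, pool)
    if (is.na(idx)) {
      abort(paste0("unknown ", root_kind, " name: ", root), class = "tpmda_index_error")
    }
    root <- idx - 1L
  }
  n_side <- if (root_kind == "mirna") nrow(R) else ncol(R)
  if (root < 0L || root >= n_side) {
    abort(sprintf("root index %d out of range for %s (0..%d)", root, root_kind, n_side - 1L),
      class = "tpmda_index_error"
    )
  }
  bt <- bfs_tree_internal(R, root_kind, as.integer(root), as.integer(max_depth))
  nodes <- tibble::tibble(
    node_id = seq_along(bt$kind),
    kind = c("mirna", "disease")[bt$kind + 1L],
    index = bt$index,
    name = ifelse(bt$kind == 0L, mirna_names[bt$index + 1L], disease_names[bt$index + 1L]),
    depth = bt$depth,
    parent = ifelse(bt$parent == 0L, NA_integer_, bt$parent)
  )
  structure(nodes,
    class = c("association_tree", class(nodes)),
    root_kind = root_kind, root_index = as.integer(root),
    n_mirna = nrow(R), n_disease = ncol(R), max_depth = as.integer(max_depth)
  )
}

# Breadth-first expansion with a visited set over both entity kinds.
# kind: 0 = mirna, 1 = disease; index: 0-based; parent: position in the
# output vectors (0 for the root). Frontier is processed in discovery order
# and children are visited in ascending index order, so parents are
# earliest-discovered and depths are shortest-path distances.
bfs_tree_internal <- function(R, root_kind, root_index, max_depth) {
  kind0 <- if (root_kind == "mirna") 0L else 1L
  m <- nrow(R); n <- ncol(R)
  kind <- integer(0); index <- integer(0); depth <- integer(0); parent <- integer(0)
  visited_m <- logical(m); visited_d <- logical(n)
  push <- function(k, i, d, p) {
    kind[[length(kind) + 1L]] <<- k
    index[[length(index) + 1L]] <<- i
    depth[[length(depth) + 1L]] <<- d
    parent[[length(parent) + 1L]] <<- p
  }
  push(kind0, root_index, 0L, 0L)
  if (kind0 == 0L) visited_m[root_index + 1L] <- TRUE else visited_d[root_index + 1L] <- TRUE
  head_pos <- 1L
  while (head_pos <= length(kind)) {
    k <- kind[head_pos]; i <- index[head_pos]; d <- depth[head_pos]
    if (d < max_depth) {
      if (k == 0L) {
        nbr <- which(R[i + 1L, ] != 0) # diseases, ascending
        nbr <- nbr[!visited_d[nbr]]
        for (j in nbr) {
          visited_d[j] <- TRUE
          push(1L, j - 1L, d + 1L, head_pos)
        }
      } else {
        nbr <- which(R[, i + 1L] != 0) # miRNAs, ascending
        nbr <- nbr[!visited_m[nbr]]
        for (j in nbr) {
          visited_m[j] <- TRUE
          push(0L, j - 1L, d + 1L, head_pos)
        }
      }
    }
    head_pos <- head_pos + 1L
  }
  list(kind = kind, index = index, depth = depth, parent = parent)
}

# Leaves in depth-first, child-order traversal order, plus the parent chain.
# children lists come from the parent vector; child order within a parent is
# discovery order (= ascending entity index).
dfs_leaves_internal <- function(parent) {
  n <- length(parent)
  children <- vector("list", n)
  for (v in seq_len(n)[-1]) children[[parent[v]]] <- c(children[[parent[v]]], v)
  leaves <- integer(0)
  stack <- 1L
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- children[[v]]
    if (is.null(ch)) leaves[[length(leaves) + 1L]] <- v else stack <- c(stack, rev(ch))
  }
  list(leaves = leaves, children = children)
}

path_to_root <- function(parent, leaf) {
  p <- leaf
  out <- integer(0)
  while (p != 0L) {
    out[[length(out) + 1L]] <- p
    p <- parent[p]
  }
  rev(out)
}

#' Extract root-to-leaf tree-paths
#'
#' Enumerates the root-to-leaf paths of an association tree — the token
#' sequences fed to the attention encoder. When the tree has at most
#' `max_paths` leaves, all paths are returned in deterministic depth-first
#' (child-order) order; otherwise `max_paths` leaves are sampled uniformly
#' without replacement under `seed`. Paths longer than `max_len` nodes are
#' truncated at `max_len` (counted from the root).
#'
#' @param tree An `association_tree` from [build_tree()].
#' @param max_paths Maximum number of paths to return (default 64).
#' @param max_len Maximum nodes per path (default 7).
#' @param seed Integer seed controlling leaf sampling (default 1).
#' @return A `tree_paths` tibble in long form: `path_id`, `step` (1-based
#'   position along the path), `kind`, `index`, `name`, `depth`.
#' @export
tree_paths <- function(tree, max_paths = 64L, max_len = 7L, seed = 1L) {
  stopifnot(inherits(tree, "association_tree"), max_paths >= 1L, max_len >= 1L)
  parent <- ifelse(is.na(tree$parent), 0L, tree$parent)
  ids <- select_path_nodes(parent, max_paths, max_len, seed)
  long <- purrr::imap_dfr(ids, function(nodes, pid) {
    tibble::tibble(
      path_id = pid, step = seq_along(nodes),
      kind = tree$kind[nodes], index = tree$index[nodes],
      name = tree$name[nodes], depth = tree$depth[nodes]
    )
  })
  structure(long,
    class = c("tree_paths", class(tibble::tibble())),
    root_kind = attr(tree, "root_kind"), root_index = attr(tree, "root_index"),
    n_mirna = attr(tree, "n_mirna"), n_disease = attr(tree, "n_disease")
  )
}

# Shared path selection: list of node-position vectors, one per chosen leaf.
select_path_nodes <- function(parent, max_paths, max_len, seed) {
  dfs <- dfs_leaves_internal(parent)
  leaves <- dfs$leaves
  if (length(leaves) > max_paths) {
    leaves <- withr::with_seed(seed, sample(leaves, max_paths))
  }
  lapply(leaves, function(lf) head(path_to_root(parent, lf), max_len))
}

# Training hot path: token-id sequences (1-based global embedding rows) of
# the sampled paths for one root entity, skipping tibble construction.
entity_path_tokens <- function(R, root_kind, root_index, max_depth, max_paths,
                               max_len, seed) {
  bt <- bfs_tree_internal(R, root_kind, root_index, max_depth)
  ids <- select_path_nodes(bt$parent, max_paths, max_len, seed)
  m <- nrow(R)
  lapply(ids, function(nodes) {
    ifelse(bt$kind[nodes] == 0L, bt$index[nodes] + 1L, m + bt$index[nodes] + 1L)
  })
}

#' @export
print.association_tree <- function(x, ...) {
  cat(sprintf(
    "<association_tree> root %s '%s', %d nodes, max depth %d\n",
    attr(x, "root_kind"), x$name[1], nrow(x), max(x$depth)
  ))
  cat(format_tree_outline(x), sep = "\n")
  invisible(x)
}

#' Plain-text outline of an association tree
#'
#' One node per line, indented by depth: `depth kind name`. Suitable for
#' writing to a file for inspection.
#'
#' @param tree An `association_tree`.
#' @return A character vector, one element per node, in depth-first order.
#' @export
format_tree_outline <- function(tree) {
  parent <- ifelse(is.na(tree$parent), 0L, tree$parent)
  dfs <- dfs_leaves_internal(parent)
  order <- integer(0)
  stack <- 1L
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order[[length(order) + 1L]] <- v
    ch <- dfs$children[[v]]
    if (!is.null(ch)) stack <- c(stack, rev(ch))
  }
  sprintf(
    "%s%d %s %s",
    strrep("  ", tree$depth[order]), tree$depth[order], tree$kind[order], tree$name[order]
  )
}

#' Write tree-paths as a TSV of node-name sequences
#'
#' @param paths A `tree_paths` tibble.
#' @param path Output file path; one line per tree-path, node names separated
#'   by tabs.
#' @return `path`, invisibly.
#' @export
write_paths_tsv <- function(paths, path) {
  stopifnot(inherits(paths, "tree_paths"))
  lines <- paths |>
    dplyr::group_by(.data$path_id) |>
    dplyr::summarise(line = paste(.data$name, collapse = "\t"), .groups = "drop")
  readr::write_lines(lines$line, path)
  invisible(path)
}
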