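#' Read a miRNA-disease association list
#'
#' Reads a plain-text, tab-separated association list: one known association
#' per line, first field the miRNA name, second field the disease name.
#' Lines starting with `#` are skipped; extra columns (evidence fields in
#' HMDD-style dumps) are ignored. Matching is case-sensitive and no
#' nomenclature normalisation is applied.
#'
#' @param path Path to the TSV file.
#' @param dedup Collapse duplicate (miRNA, disease) lines to one pair
#'   (default `TRUE`).
#' @return A tibble with character columns `mirna` and `disease`, one row per
#'   (retained) association, in file order.
#' @seealso [association_dataset()] to index the pairs into a dataset.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("m1\td1", "m2\td1", "m2\td2", "m2\td1"), tf)
#' read_associations(tf)
read_associations <- function(path, dedup = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("association file not found: ", path), class = "tpmda_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort("no associations: file contains no data lines", class = "tpmda_parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 2L || !nzchar(f[1]) || !nzchar(f[2]), logical(1)))
  if (length(bad) > 0L) {
    abort(
      sprintf("malformed association line %d: expected >= 2 tab-separated fields", line_no[bad[1]]),
      class = "tpmda_parse_error"
    )
  }
  out <- tibble::tibble(
    mirna = vapply(fields, `[[`, character(1), 1L),
    disease = vapply(fields, `[[`, character(1), 2L)
  )
  if (dedup) out <- dplyr::distinct(out, .data$mirna, .data$disease)
  out
}

#' Build an indexed association dataset from a pair table
#'
#' Indexes a two-column association table into an `association_dataset`: the
#' ordered entity name lists M and D (first-occurrence order), the deduplicated
#' pair set with 0-based indices, and accessors for the m x n binary
#' association matrix R, where `R[i, j] = 1` iff miRNA i is known to associate
#' with disease j and 0 where the relationship is unknown.
#'
#' @param pairs A data frame with character columns `mirna` and `disease`
#'   (e.g. from [read_associations()]).
#' @param dedup Collapse duplicate pairs (default `TRUE`). With
#'   `dedup = FALSE`, duplicated pairs raise an error rather than silently
#'   violating the pair-set invariant.
#' @return An `association_dataset` object with fields `mirna_names`,
#'   `disease_names` and `pairs` (tibble of `mirna_idx`, `disease_idx`,
#'   0-based, ordered).
#' @export
#' @examples
#' df <- tibble::tibble(mirna = c("m1", "m2", "m2"), disease = c("d1", "d1", "d2"))
#' ds <- association_dataset(df)
#' glance(ds)
association_dataset <- function(pairs, dedup = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    abort("no associations: empty pair table", class = "tpmda_parse_error")
  }
  pairs <- tibble::as_tibble(pairs)[, c("mirna", "disease")]
  if (dedup) {
    pairs <- dplyr::distinct(pairs)
  } else if (anyDuplicated(pairs)) {
    abort("duplicate pairs present and dedup = FALSE", class = "tpmda_validation_error")
  }
  mirna_names <- unique(pairs$mirna)
  disease_names <- unique(pairs$disease)
  out <- structure(
    list(
      mirna_names = mirna_names,
      disease_names = disease_names,
      pairs = tibble::tibble(
        mirna_idx = match(pairs$mirna, mirna_names) - 1L,
        disease_idx = match(pairs$disease, disease_names) - 1L
      )
    ),
    class = "association_dataset"
  )
  out
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "<association_dataset> %d miRNAs x %d diseases, %d known pairs (density %.4f%%)\n",
    n_mirna(x), n_disease(x), n_pairs(x), 100 * density(x)
  ))
  invisible(x)
}

#' Dataset dimensions and density
#'
#' `n_mirna()`, `n_disease()` and `n_pairs()` return the entity and pair
#' counts; `density()` returns the correlation rate |pairs| / (m * n), the
#' fraction of the m x n matrix that is a known association.
#'
#' @param x An `association_dataset`.
#' @param ... Unused.
#' @return A single number.
#' @export
n_mirna <- function(x) length(x$mirna_names)

#' @rdname n_mirna
#' @export
n_disease <- function(x) length(x$disease_names)

#' @rdname n_mirna
#' @export
n_pairs <- function(x) nrow(x$pairs)

#' @rdname n_mirna
#' @export
density.association_dataset <- function(x, ...) {
  n_pairs(x) / (n_mirna(x) * n_disease(x))
}

#' @export
glance.association_dataset <- function(x, ...) {
  tibble::tibble(
    n_mirna = n_mirna(x),
    n_disease = n_disease(x),
    n_pairs = n_pairs(x),
    density = density(x)
  )
}

#' @export
tidy.association_dataset <- function(x, ...) {
  dplyr::mutate(
    x$pairs,
    mirna = x$mirna_names[.data$mirna_idx + 1L],
    disease = x$disease_names[.data$disease_idx + 1L],
    .before = 1L
  )
}

#' Build the binary association matrix R
#'
#' Materialises the m x n 0/1 matrix with `R[i, j] = 1` iff the (i, j)
#' association is known. Row and column names carry the entity names.
#'
#' @param x An `association_dataset`.
#' @return A base `matrix` of 0/1 with `dimnames = list(mirna, disease)`.
#' @export
association_matrix <- function(x) {
  stopifnot(inherits(x, "association_dataset"))
  R <- matrix(0L, n_mirna(x), n_disease(x),
    dimnames = list(x$mirna_names, x$disease_names)
  )
  R[cbind(x$pairs$mirna_idx + 1L, x$pairs$disease_idx + 1L)] <- 1L
  R
}

#' Enumerate the unknown (zero) cells of the association matrix
#'
#' @param x An `association_dataset`.
#' @return A tibble of 0-based `mirna_idx`, `disease_idx` for every cell with
#'   `R[i, j] == 0`, in row-major order; `m * n - |pairs|` rows.
#' @export
unknown_pairs <- function(x) {
  stopifnot(inherits(x, "association_dataset"))
  m <- n_mirna(x); n <- n_disease(x)
  all_cells <- tidyr::expand_grid(mirna_idx = 0:(m - 1L), disease_idx = 0:(n - 1L))
  dplyr::anti_join(all_cells, x$pairs, by = c("mirna_idx", "disease_idx"))
}

#' Write an association dataset back to TSV
#'
#' Writes the same two-column tab-separated dialect that
#' [read_associations()] consumes, so a write/read round-trip preserves the
#' pair set and name order.
#'
#' @param x An `association_dataset` or a `mirna`/`disease` pair table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  df <- if (inherits(x, "association_dataset")) tidy(x) else tibble::as_tibble(x)
  readr::write_tsv(df[, c("mirna", "disease")], path, col_names = FALSE)
  invisible(path)
}

#' Export the association matrix as MatrixMarket sparse triplets
#'
#' @param x An `association_dataset`.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_matrix_market <- function(x, path) {
  stopifnot(inherits(x, "association_dataset"))
  sp <- Matrix::sparseMatrix(
    i = x$pairs$mirna_idx + 1L, j = x$pairs$disease_idx + 1L, x = 1,
    dims = c(n_mirna(x), n_disease(x))
  )
  Matrix::writeMM(sp, path)
  invisible(path)
}
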