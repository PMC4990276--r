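#' Pairwise fractional identity
#'
#' For equal-length sequences the identity is the fraction of matching
#' positions (1 - Hamming distance / length). For unequal lengths a global
#' end-to-end alignment is computed with fixed scores (match +1, mismatch -1,
#' gap -2, no end-gap discount) and the identity is matching columns /
#' alignment columns; traceback ties prefer the diagonal, then the vertical
#' move, so the value is deterministic. This internal definition is a
#' documented substitute for, not a claim of equivalence with, USEARCH's
#' "-id" formulae.
#'
#' @param a,b non-empty ACGT strings.
#' @return A fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA") # 0.75
#' @export
pairwise_identity <- function(a, b) {
  check_bases(toupper(c(a, b)))
  nw_identity_cpp(toupper(a), toupper(b))
}

#' All-pairs identity matrix
#'
#' @param records a sequence tibble (or a character vector of ACGT strings).
#' @return A symmetric numeric matrix in `[0, 1]` with unit diagonal and the
#'   record ids as dimnames.
#' @export
identity_matrix <- function(records) {
  if (is.character(records)) {
    records <- seq_tbl(id = paste0("s", seq_along(records)), bases = records)
  }
  validate_seqs(records)
  if (nrow(records) == 0) abort("at least one record is required")
  m <- identity_matrix_cpp(records$bases)
  dimnames(m) <- list(records$id, records$id)
  m
}

#' Write an identity matrix as TSV
#'
#' @param matrix an [identity_matrix()].
#' @param path output path; the first row is the id header.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Deterministic guide order for ring arrangement
#'
#' Leaf order of an average-linkage (UPGMA, distance = 1 - identity)
#' hierarchy over the records, built with deterministic tie-breaking: at each
#' step the pair with the highest mean identity merges, ties resolving to the
#' lexicographically smallest index pair, and at each internal node the child
#' containing the smallest original index is placed first. Adjacent positions
#' in the order therefore correspond to high-identity neighbourhoods; the
#' order plays the role a guide-tree-ordered multiple alignment plays when
#' arranging heat map rings.
#'
#' @param matrix an [identity_matrix()].
#' @return An integer permutation of `1:n` (attribute `ids` carries the
#'   record ids in guide order).
#' @export
guide_order <- function(matrix) {
  n <- nrow(matrix)
  stopifnot(n >= 1, n == ncol(matrix))
  if (n == 1) {
    return(structure(1L, ids = rownames(matrix)))
  }
  merges <- merge_tree_cpp(matrix, 3L, .id_tol)
  leaves <- as.list(seq_len(n))
  for (k in seq_len(nrow(merges))) {
    a <- as.integer(merges[k, 1]) # a < b, and a is the smallest member of
    b <- as.integer(merges[k, 2]) # the merged cluster: place its child first
    leaves[[a]] <- c(leaves[[a]], leaves[[b]])
    leaves[[b]] <- NULL_leaf
  }
  ord <- leaves[[1]]
  structure(as.integer(ord), ids = rownames(matrix)[ord])
}

NULL_leaf <- integer(0)

#' Staggered (ends-alternating) input order
#'
#' Reorders a guide order by alternating between its two ends: first element,
#' last, second, second-to-last, ... (the middle element of an odd-length
#' order comes last). Processing sequences in this order seeds greedy
#' centroid clustering with the most mutually distant - and therefore
#' potentially cluster-splitting - sequences first.
#'
#' @param order an integer vector (typically from [guide_order()]).
#' @return A permutation of `order`.
#' @examples
#' staggered_order(1:5) # 1 5 2 4 3
#' @export
staggered_order <- function(order) {
  n <- length(order)
  if (n <= 1) return(order)
  lo <- order[seq_len(ceiling(n / 2))]
  hi <- rev(order[(ceiling(n / 2) + 1L):n])
  out <- integer(n)
  out[seq(1L, 2L * length(hi), by = 2L)] <- lo[seq_along(hi)]
  out[seq(2L, 2L * length(hi), by = 2L)] <- hi
  if (n %% 2L == 1L) out[n] <- lo[length(lo)]
  out
}

#' Export a guide order as one id per line
#'
#' @param order result of [guide_order()] (must carry the `ids` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guide_order <- function(order, path) {
  ids <- attr(order, "ids")
  if (is.null(ids)) abort("order carries no ids")
  writeLines(ids, path)
  invisible(path)
}
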