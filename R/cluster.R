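#' Cutoff ladder
#'
#' The ascending fractional-identity cutoffs at which the sequence set is
#' partitioned, one heat map ring per cutoff. The default ladder is 0.75,
#' 0.76, ..., 1.00 (26 levels).
#'
#' @param lo,hi first and last cutoff, in (0, 1].
#' @param step cutoff increment.
#' @return A strictly increasing numeric vector of cutoffs.
#' @export
cutoff_ladder <- function(lo = 0.75, hi = 1.00, step = 0.01) {
  stopifnot(lo > 0, hi <= 1, lo <= hi, step > 0)
  cutoffs <- seq(lo, hi, by = step)
  stopifnot(all(diff(cutoffs) > 0))
  cutoffs
}

linkage_code <- function(linkage) {
  switch(linkage, min = 1L, max = 2L, avg = 3L,
         abort(sprintf("unknown linkage '%s'", linkage)))
}

#' Agglomerative merge tree
#'
#' Repeatedly merges the cluster pair with the highest linkage identity until
#' one cluster remains. The linkage identity between two clusters is the
#' maximum cross-pair identity for `"min"` (single linkage: one agreeing edge
#' suffices to join), the minimum for `"max"` (complete linkage: every edge
#' must agree) and the unweighted mean over all cross pairs for `"avg"`
#' (UPGMA). Ties resolve to the lexicographically smallest
#' (minimum-member-index) pair, so the tree is fully deterministic.
#'
#' @param matrix an [identity_matrix()].
#' @param linkage `"min"`, `"max"` or `"avg"`.
#' @return A `merge_tree`: list with `merges` (tibble `a`, `b`, `identity`;
#'   `a`/`b` are the minimum member indices of the merging clusters, with the
#'   linkage identity recorded at merge time), `ids`, `n`, `linkage`.
#' @export
agglomerative_merge_tree <- function(matrix,
                                     linkage = c("min", "max", "avg")) {
  linkage <- match.arg(linkage)
  n <- nrow(matrix)
  stopifnot(n >= 1, n == ncol(matrix))
  m <- merge_tree_cpp(matrix, linkage_code(linkage), .id_tol)
  merges <- tibble(a = as.integer(m[, 1]), b = as.integer(m[, 2]),
                   identity = m[, 3])
  structure(list(merges = merges, ids = rownames(matrix), n = n,
                 linkage = linkage),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %s linkage, %d leaves, %d merges\n",
              x$linkage, x$n, nrow(x$merges)))
  invisible(x)
}

#' Cut a merge tree at an identity cutoff
#'
#' Applies exactly those merges whose linkage identity meets the cutoff
#' (identity >= cutoff joins, matching the minimum-identity semantics of an
#' identity threshold). Merges below the cutoff are the "non-joining cluster
#' segments" seen with complete and average linkage.
#'
#' @param tree an [agglomerative_merge_tree()].
#' @param cutoff fraction in (0, 1].
#' @return An integer membership vector: `membership[i]` is the cluster of
#'   record i, clusters numbered 1, 2, ... by their smallest member index.
#' @export
cut_at <- function(tree, cutoff) {
  stopifnot(inherits(tree, "merge_tree"), cutoff > 0, cutoff <= 1)
  parent <- seq_len(tree$n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- tree$merges$identity >= cutoff - .id_tol
  for (k in which(keep)) {
    ra <- find(tree$merges$a[k])
    rb <- find(tree$merges$b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(tree$n), find, integer(1))
  as.integer(factor(roots, levels = unique(sort(roots))))
}

group_tally <- function(member_list, records, group) {
  unname(vapply(member_list, function(m) {
    sum(records$count[m][records$group[m] == group])
  }, numeric(1)))
}

ring_from_membership <- function(membership, records, centroids = NULL) {
  member_list <- unname(split(seq_along(membership), membership))
  tibble(
    cluster_id = seq_along(member_list),
    members = member_list,
    centroid = if (is.null(centroids)) NA_integer_ else as.integer(centroids),
    n_members = lengths(member_list),
    g1 = group_tally(member_list, records, "group1"),
    g2 = group_tally(member_list, records, "group2")
  )
}

new_cluster_ladder <- function(rings, records, method, cutoffs) {
  structure(list(rings = rings, records = records, method = method,
                 cutoffs = cutoffs),
            class = "cluster_ladder")
}

#' Build a nested cluster ladder from an agglomerative merge tree
#'
#' Cuts one merge tree at every cutoff of the ladder. Because min, max and
#' avg linkage identities are monotone along the merge sequence, the per-ring
#' partitions nest: every cluster at a stricter cutoff is contained in
#' exactly one cluster at the next looser cutoff, and cluster counts are
#' non-decreasing with the cutoff.
#'
#' @param records a sequence tibble with groups assigned (typically
#'   dereplicated; identical sequences always co-cluster, so dereplication
#'   changes abundances only).
#' @param linkage `"min"`, `"max"` or `"avg"`.
#' @param cutoffs a [cutoff_ladder()].
#' @param matrix optional precomputed [identity_matrix()] of `records`.
#' @return A `cluster_ladder`: list with `rings` (tibble: `level`, `cutoff`,
#'   `cluster_id`, `parent_id`, `members` list-column of record row indices,
#'   `centroid`, `n_members`, `g1`, `g2`), `records`, `method`, `cutoffs`.
#' @export
build_agglomerative_ladder <- function(records,
                                       linkage = c("min", "max", "avg"),
                                       cutoffs = cutoff_ladder(),
                                       matrix = NULL) {
  linkage <- match.arg(linkage)
  validate_seqs(records)
  if (anyNA(records$group)) abort("records need group labels; see assign_groups()")
  if (is.null(matrix)) matrix <- identity_matrix(records)
  tree <- agglomerative_merge_tree(matrix, linkage)
  rings <- vector("list", length(cutoffs))
  prev_membership <- NULL
  for (l in seq_along(cutoffs)) {
    membership <- cut_at(tree, cutoffs[l])
    ring <- ring_from_membership(membership, records)
    ring$level <- l
    ring$cutoff <- cutoffs[l]
    ring$parent_id <- if (l == 1) NA_integer_ else
      prev_membership[vapply(ring$members, `[`, integer(1), 1L)]
    rings[[l]] <- ring
    prev_membership <- membership
  }
  ladder <- new_cluster_ladder(order_ring_cols(bind_rows(rings)), records,
                               linkage, cutoffs)
  assert_ladder(ladder)
  ladder
}

order_ring_cols <- function(rings) {
  rings[, c("level", "cutoff", "cluster_id", "parent_id", "members",
            "centroid", "n_members", "g1", "g2")]
}

#' Greedy centroid partition of an ordered sequence set
#'
#' Processes records in their given order (the caller applies
#' [staggered_order()] first). The first record founds cluster 1 and becomes
#' its centroid; each later record is compared against all existing centroids
#' and joins the one of highest identity when that identity meets the cutoff,
#' otherwise it founds a new cluster as its centroid. Centroid ties resolve
#' to the earliest-founded cluster.
#'
#' @param records a sequence tibble, already in processing order.
#' @param cutoff identity cutoff in (0, 1].
#' @return A tibble with one row per cluster in founding order: `cluster_id`,
#'   `members` (row indices into `records`, in processing order), `centroid`
#'   (row index of the centroid), `n_members`, `g1`, `g2`.
#' @export
greedy_centroid_partition <- function(records, cutoff) {
  validate_seqs(records)
  stopifnot(nrow(records) >= 1, cutoff > 0, cutoff <= 1)
  if (anyNA(records$group)) abort("records need group labels; see assign_groups()")
  res <- greedy_assign_cpp(records$bases, seq_len(nrow(records)), cutoff,
                           .id_tol)
  ring <- ring_from_membership_founding(res$cluster, res$centroids, records)
  ring
}

ring_from_membership_founding <- function(membership, centroids, records) {
  # split() by the integer membership orders elements by cluster id, which
  # is founding order here
  member_list <- unname(split(seq_along(membership), membership))
  tibble(
    cluster_id = seq_along(member_list),
    members = member_list,
    centroid = as.integer(centroids),
    n_members = lengths(member_list),
    g1 = group_tally(member_list, records, "group1"),
    g2 = group_tally(member_list, records, "group2")
  )
}

#' Build a nested cluster ladder by top-down greedy centroid refinement
#'
#' Stepwise divisive clustering: the loosest cutoff partitions the full
#' record set with [greedy_centroid_partition()] over the staggered guide
#' order; each subsequent cutoff independently re-partitions every cluster of
#' the previous level, processing its members in the (restricted) staggered
#' order. Parent links are recorded directly, so nesting holds by
#' construction. No all-pairs identity matrix is required by the clustering
#' itself (sequences are only ever compared to current centroids).
#'
#' @param records a sequence tibble with groups assigned (typically
#'   dereplicated).
#' @param cutoffs a [cutoff_ladder()].
#' @param order a [guide_order()] over `records`.
#' @param recompute_order recompute the staggered order from a fresh
#'   per-cluster guide order at every refinement step (default `FALSE`:
#'   the full-dataset staggered order is restricted to each cluster's
#'   members).
#' @return A `cluster_ladder` (see [build_agglomerative_ladder()]) with
#'   `method = "centroid"` and per-cluster centroids recorded.
#' @export
build_divisive_ladder <- function(records, cutoffs = cutoff_ladder(),
                                  order = NULL, recompute_order = FALSE) {
  validate_seqs(records)
  if (anyNA(records$group)) abort("records need group labels; see assign_groups()")
  n <- nrow(records)
  if (is.null(order)) order <- guide_order(identity_matrix(records))
  stopifnot(length(order) == n)

  stag <- staggered_order(order)
  partition_members <- function(members) {
    # members must arrive in processing order
    res <- greedy_assign_cpp(records$bases, members,
                             cutoffs[[lvl]], .id_tol)
    lapply(unname(split(seq_along(members), res$cluster)),
           function(ix) members[ix])
  }
  restricted <- function(members) stag[stag %in% members]
  local_stagger <- function(members) {
    if (length(members) <= 2) return(members)
    sub <- identity_matrix_cpp(records$bases[members])
    members[staggered_order(guide_order(sub))]
  }

  rings <- vector("list", length(cutoffs))
  lvl <- 1L
  clusters <- partition_members(stag) # founding order at the base cutoff
  centroids <- vapply(clusters, `[`, integer(1), 1L)
  parent_ids <- rep(NA_integer_, length(clusters))
  repeat {
    # number clusters within the ring by smallest member index, matching the
    # agglomerative rings; keep clusters/centroids aligned with those ids
    ord <- order(vapply(clusters, min, integer(1)))
    clusters <- clusters[ord]
    centroids <- centroids[ord]
    parent_ids <- parent_ids[ord]
    ring <- divisive_ring(clusters, centroids, parent_ids, records)
    ring$level <- lvl
    ring$cutoff <- cutoffs[lvl]
    rings[[lvl]] <- ring
    if (lvl == length(cutoffs)) break
    lvl <- lvl + 1L
    new_clusters <- list()
    new_centroids <- integer(0)
    new_parents <- integer(0)
    for (p in seq_along(clusters)) {
      mem <- clusters[[p]]
      ord_p <- if (recompute_order) local_stagger(sort(mem)) else
        restricted(mem)
      subs <- partition_members(ord_p)
      new_clusters <- c(new_clusters, subs)
      new_centroids <- c(new_centroids,
                         vapply(subs, `[`, integer(1), 1L))
      new_parents <- c(new_parents, rep(ring$cluster_id[p], length(subs)))
    }
    clusters <- new_clusters
    centroids <- new_centroids
    parent_ids <- new_parents
  }
  ladder <- new_cluster_ladder(order_ring_cols(bind_rows(rings)), records,
                               "centroid", cutoffs)
  assert_ladder(ladder)
  ladder
}

divisive_ring <- function(clusters, centroids, parent_ids, records) {
  member_list <- unname(lapply(clusters, sort))
  tibble(
    cluster_id = seq_along(member_list),
    members = member_list,
    centroid = as.integer(unname(centroids)),
    parent_id = as.integer(unname(parent_ids)),
    n_members = lengths(member_list),
    g1 = group_tally(member_list, records, "group1"),
    g2 = group_tally(member_list, records, "group2")
  )
}

assert_ladder <- function(ladder) {
  n <- nrow(ladder$records)
  rings <- ladder$rings
  prev <- NULL
  for (l in unique(rings$level)) {
    ring <- rings[rings$level == l, ]
    got <- sort(unname(unlist(ring$members)))
    if (!identical(got, seq_len(n))) {
      abort(sprintf("ring at level %d is not a partition", l))
    }
    if (!is.null(prev) && nrow(ring) < nrow(prev)) {
      abort("cluster counts decreased with the cutoff")
    }
    if (!is.null(prev)) {
      for (k in seq_len(nrow(ring))) {
        pid <- ring$parent_id[k]
        if (is.na(pid) ||
            !all(ring$members[[k]] %in%
                 prev$members[[match(pid, prev$cluster_id)]])) {
          abort(sprintf("cluster %d at level %d is not nested in its parent",
                        ring$cluster_id[k], l))
        }
      }
    }
    prev <- ring
  }
  invisible(ladder)
}

#' @export
print.cluster_ladder <- function(x, ...) {
  counts <- table(x$rings$level)
  cat(sprintf("<cluster_ladder> %s method, %d records, %d levels (%g..%g), %d..%d clusters\n",
              x$method, nrow(x$records), length(x$cutoffs),
              min(x$cutoffs), max(x$cutoffs),
              min(counts), max(counts)))
  invisible(x)
}

#' @export
tidy.cluster_ladder <- function(x, ...) {
  out <- x$rings
  out$members <- NULL
  as_tibble(out)
}

#' @export
glance.cluster_ladder <- function(x, ...) {
  base <- x$rings[x$rings$level == 1, ]
  top <- x$rings[x$rings$level == max(x$rings$level), ]
  tibble(method = x$method, n_records = nrow(x$records),
         total_abundance = sum(x$records$count),
         n_levels = length(x$cutoffs),
         n_clusters_base = nrow(base), n_clusters_final = nrow(top))
}
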