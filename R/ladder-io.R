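#' Export / import a cluster ladder as TSV
#'
#' One row per cluster:
#' `cutoff<TAB>cluster_id<TAB>parent_cluster_id<TAB>member_ids<TAB>g1<TAB>g2`
#' with member ids comma-separated. A leading `# method=<method>` comment
#' records the clustering method so the ladder can be reconstructed.
#'
#' @param ladder a `cluster_ladder`.
#' @param path output path.
#' @return `write_ladder_tsv()`: `path` invisibly; `read_ladder_tsv()`: a
#'   `cluster_ladder` (the `records` table is rebuilt with placeholder bases
#'   and per-member unit counts are not recoverable, so only ring structure,
#'   ids and group tallies round-trip).
#' @export
write_ladder_tsv <- function(ladder, path) {
  stopifnot(inherits(ladder, "cluster_ladder"))
  rings <- ladder$rings
  ids <- ladder$records$id
  lines <- c(
    sprintf("# method=%s", ladder$method),
    "cutoff\tcluster_id\tparent_cluster_id\tmember_ids\tg1\tg2",
    sprintf("%s\t%d\t%s\t%s\t%g\t%g",
            format(rings$cutoff, trim = TRUE),
            rings$cluster_id,
            ifelse(is.na(rings$parent_id), "NA",
                   as.character(rings$parent_id)),
            vapply(rings$members, function(m) {
              paste(ids[m], collapse = ",")
            }, character(1)),
            rings$g1, rings$g2)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ladder_tsv
#' @export
read_ladder_tsv <- function(path) {
  lines <- readLines(path)
  method <- sub("^# method=", "", lines[1])
  body <- utils::read.delim(text = lines[-1], colClasses = "character")
  cutoffs <- sort(unique(as.numeric(body$cutoff)))
  levels <- match(as.numeric(body$cutoff), cutoffs)
  base <- body[levels == 1, , drop = FALSE]
  ids <- unlist(strsplit(base$member_ids, ",", fixed = TRUE))
  records <- tibble(id = ids, bases = NA_character_, group = NA_character_,
                    count = 1L, events = 0L)
  rings <- tibble(
    level = levels,
    cutoff = as.numeric(body$cutoff),
    cluster_id = as.integer(body$cluster_id),
    parent_id = suppressWarnings(as.integer(body$parent_cluster_id)),
    members = lapply(strsplit(body$member_ids, ",", fixed = TRUE),
                     function(m) sort(match(m, ids))),
    centroid = NA_integer_,
    g1 = as.numeric(body$g1),
    g2 = as.numeric(body$g2)
  )
  rings$n_members <- lengths(rings$members)
  rings <- order_ring_cols(rings)
  new_cluster_ladder(rings, records, method, cutoffs)
}
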