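#' Arrange the clusters of one ring for display
#'
#' Base ring: clusters sort by the minimum guide-order rank of their members,
#' so high-identity neighbourhoods sit side by side. Deeper rings: children
#' are grouped under their parent in the parent's display order (children of
#' distinct parents never interleave) and sort by minimum guide-order rank
#' within each parent.
#'
#' @param ring one level of a `cluster_ladder`'s `rings` tibble.
#' @param order a [guide_order()] over the ladder's records.
#' @param parent_order optional integer vector of parent `cluster_id`s in
#'   display order (required for non-base rings).
#' @return The ring's `cluster_id`s in display order.
#' @export
order_ring_clusters <- function(ring, order, parent_order = NULL) {
  rank <- integer(length(order))
  rank[order] <- seq_along(order)
  min_rank <- vapply(ring$members, function(m) min(rank[m]), numeric(1))
  if (is.null(parent_order)) {
    return(ring$cluster_id[base::order(min_rank)])
  }
  pos <- match(ring$parent_id, parent_order)
  ring$cluster_id[base::order(pos, min_rank)]
}

#' Assign angular spans to ordered ladder rings
#'
#' The key wedge is centered at 0 degrees (12 o'clock; angles run clockwise)
#' and the remaining `360 - wedge_extent` degrees hold the clusters. Base
#' ring spans are proportional to cluster weight; every deeper ring
#' partitions each parent's span among its children proportionally to child
#' weight, so child spans nest exactly inside their parent's and per-ring
#' extents always sum to `360 - wedge_extent`.
#'
#' @param rings a `rings` tibble (all levels) whose rows are already in
#'   display order within each level, with a `weight` column.
#' @param wedge_extent key-wedge extent in degrees, in (0, 90].
#' @return `rings` with `start_deg` and `extent_deg` columns added.
#' @keywords internal
assign_spans <- function(rings, wedge_extent) {
  stopifnot(wedge_extent > 0, wedge_extent <= 90)
  available <- 360 - wedge_extent
  arc_start <- wedge_extent / 2
  out <- vector("list", length(unique(rings$level)))
  prev <- NULL
  for (l in sort(unique(rings$level))) {
    ring <- rings[rings$level == l, ]
    total <- sum(ring$weight)
    if (total <= 0) abort("total abundance is zero")
    if (is.null(prev)) {
      ring$extent_deg <- available * ring$weight / total
      ring$start_deg <- arc_start + cumsum(c(0, ring$extent_deg))[
        seq_len(nrow(ring))]
    } else {
      ring$start_deg <- NA_real_
      ring$extent_deg <- NA_real_
      for (p in seq_len(nrow(prev))) {
        kids <- which(ring$parent_id == prev$cluster_id[p])
        w <- ring$weight[kids]
        ext <- prev$extent_deg[p] * w / sum(w)
        ring$extent_deg[kids] <- ext
        ring$start_deg[kids] <- prev$start_deg[p] +
          cumsum(c(0, ext))[seq_along(kids)]
      }
    }
    out[[match(l, sort(unique(rings$level)))]] <- ring
    prev <- ring
  }
  bind_rows(out)
}

#' Build the radial geometry of a dendritic heat map
#'
#' Orders every ring with [order_ring_clusters()] and assigns
#' count-proportional angular spans with parent-span conservation: a
#' sequence's angular interval at one ring always contains its interval at
#' the next, so radial position is preserved from the centre out to the
#' circumference. Rings run innermost = loosest cutoff to outermost =
#' strictest.
#'
#' @param ladder a `cluster_ladder`.
#' @param order a [guide_order()] over the ladder's records.
#' @param wedge_deg key-wedge extent in degrees (default 12).
#' @param width_by `"abundance"` (dereplicated counts, the default) or
#'   `"unique"` (distinct-sequence counts) for angular weights.
#' @param inner_radius inner hole radius as a fraction of the outer radius.
#' @return A `dhm_layout`: tibble (`level`, `cutoff`, `cluster_id`,
#'   `parent_id`, `weight`, `g1`, `g2`, `start_deg`, `extent_deg`) with
#'   attributes `wedge` (start/extent), `inner_radius`, `width_by` and
#'   `n_levels`.
#' @export
build_layout <- function(ladder, order, wedge_deg = 12,
                         width_by = c("abundance", "unique"),
                         inner_radius = 0.15) {
  stopifnot(inherits(ladder, "cluster_ladder"))
  width_by <- match.arg(width_by)
  stopifnot(inner_radius > 0, inner_radius < 1)
  rings <- ladder$rings
  rings$weight <- if (width_by == "abundance") rings$g1 + rings$g2 else
    as.numeric(rings$n_members)

  ordered <- vector("list", length(ladder$cutoffs))
  parent_disp <- NULL
  for (l in seq_along(ladder$cutoffs)) {
    ring <- rings[rings$level == l, ]
    disp <- order_ring_clusters(ring, order, parent_disp)
    ordered[[l]] <- ring[match(disp, ring$cluster_id), ]
    parent_disp <- disp
  }
  geo <- assign_spans(bind_rows(ordered), wedge_deg)
  geo$members <- NULL
  geo <- as_tibble(geo[, c("level", "cutoff", "cluster_id", "parent_id",
                           "n_members", "weight", "g1", "g2",
                           "start_deg", "extent_deg")])
  structure(geo,
            wedge = c(start = 360 - wedge_deg / 2, extent = wedge_deg),
            inner_radius = inner_radius,
            width_by = width_by,
            n_levels = length(ladder$cutoffs),
            class = c("dhm_layout", class(geo)))
}

#' Export a layout as TSV
#'
#' One `level<TAB>cluster_id<TAB>start_deg<TAB>extent_deg` row per laid-out
#' cluster.
#'
#' @param layout a [build_layout()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  stopifnot(inherits(layout, "dhm_layout"))
  lines <- c("level\tcluster_id\tstart_deg\textent_deg",
             sprintf("%d\t%d\t%.6f\t%.6f", layout$level, layout$cluster_id,
                     layout$start_deg, layout$extent_deg))
  writeLines(lines, path)
  invisible(path)
}
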