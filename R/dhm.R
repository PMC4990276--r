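#' Build a dendritic heat map from a sequence table
#'
#' Runs the full method: GC-content group assignment (unless groups are
#' already present), dereplication with abundance counts, all-pairs
#' fractional identities, the deterministic guide order, the chosen
#' clustering ladder over the cutoff range, radial layout with parent-span
#' conservation, and per-cluster log-ratio bin responses. The result is
#' plotted with [autoplot()], rendered with [dhm_render_svg()] or exported
#' with [dhm_export_circos()].
#'
#' @param records a sequence tibble (see [seq_tbl()]); the `group` column is
#'   filled from GC content when absent.
#' @param method `"centroid"` (top-down greedy, the default and the
#'   recommended choice for large data), `"min"`, `"max"` or `"avg"`
#'   (bottom-up agglomerative linkages).
#' @param cutoffs a [cutoff_ladder()].
#' @param wedge_deg key-wedge extent in degrees.
#' @param width_by `"abundance"` or `"unique"` angular weighting.
#' @param group_map optional [read_group_map()] table of external phenotype
#'   labels.
#' @return A `dhm` object: list with `records` (dereplicated), `matrix`,
#'   `order`, `ladder`, `layout`, `responses`, `method`.
#' @examples
#' \donttest{
#' gs <- simulate_mutation_lineage(n_seqs = 20, iterations = 5, seed = 1)
#' d <- dhm_build(gs$snapshots[[6]], method = "avg")
#' tidy(d)
#' }
#' @export
dhm_build <- function(records, method = c("centroid", "min", "max", "avg"),
                      cutoffs = cutoff_ladder(), wedge_deg = 12,
                      width_by = c("abundance", "unique"),
                      group_map = NULL) {
  method <- match.arg(method)
  width_by <- match.arg(width_by)
  validate_seqs(records)
  if (anyNA(records$group) || !is.null(group_map)) {
    records <- assign_groups(records, group_map)
  }
  derep <- dereplicate(records)
  im <- identity_matrix(derep)
  ord <- guide_order(im)
  ladder <- if (method == "centroid") {
    build_divisive_ladder(derep, cutoffs, ord)
  } else {
    build_agglomerative_ladder(derep, method, cutoffs, matrix = im)
  }
  layout <- build_layout(ladder, ord, wedge_deg = wedge_deg,
                         width_by = width_by)
  structure(
    list(records = derep, matrix = im, order = ord, ladder = ladder,
         layout = layout, responses = bin_responses(ladder),
         method = method),
    class = "dhm"
  )
}

#' @export
print.dhm <- function(x, ...) {
  cat(sprintf("<dhm> %s method, %d unique sequences (abundance %d), %d rings\n",
              x$method, nrow(x$records), sum(x$records$count),
              length(x$ladder$cutoffs)))
  invisible(x)
}

#' @export
tidy.dhm <- function(x, scale = NULL, ...) {
  M <- if (is.null(scale)) normalization_scale(x$responses$r) else scale
  out <- left_join(as_tibble(x$layout),
                   x$responses[, c("level", "cluster_id", "r")],
                   by = c("level", "cluster_id"))
  out$category <- category_of(out$r, M)
  out
}

#' @export
glance.dhm <- function(x, ...) {
  g <- glance(x$ladder)
  g$max_abs_response <- normalization_scale(x$responses$r)
  g
}

dhm_colours <- function(x, M, palette) {
  cats <- category_of(x$responses$r, M)
  tibble(level = x$responses$level, cluster_id = x$responses$cluster_id,
         colour = color_of(cats, palette))
}

#' Render a dendritic heat map to SVG
#'
#' @param x a [dhm_build()] result.
#' @param path output SVG path.
#' @param scale normalization scale M; default the panel's own maximum
#'   absolute response. Pass [normalization_scale()] over all panels of a
#'   figure set to share hues between panels.
#' @param palette a [dhm_palette()].
#' @param config a [render_config()].
#' @return `path`, invisibly.
#' @export
dhm_render_svg <- function(x, path, scale = NULL, palette = dhm_palette(),
                           config = render_config()) {
  stopifnot(inherits(x, "dhm"))
  M <- if (is.null(scale)) normalization_scale(x$responses$r) else scale
  render_svg(x$layout, dhm_colours(x, M, palette), path, config,
             key_colours = c(palette$key_max, palette$key_min))
}

#' Export a dendritic heat map as Circos input files
#'
#' @param x a [dhm_build()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
dhm_export_circos <- function(x, out_dir) {
  stopifnot(inherits(x, "dhm"))
  export_circos(x$layout, x$responses, out_dir)
}

#' Plot a dendritic heat map with ggplot2
#'
#' Rings are drawn as stacked rectangles in polar coordinates: angle = the
#' layout's clockwise-from-12-o'clock degrees, radius = ring level (plus the
#' inner hole), fill = the 23-category diverging colour of each cluster's
#' bin response. The key wedge at 0 degrees shows the two extremes.
#'
#' @param object a `dhm`.
#' @param scale normalization scale M (default: panel-local).
#' @param palette a [dhm_palette()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dhm <- function(object, scale = NULL, palette = dhm_palette(),
                         ...) {
  M <- if (is.null(scale)) normalization_scale(object$responses$r) else scale
  dat <- tidy(object, scale = M)
  dat$colour <- color_of(dat$category, palette)
  n_levels <- attr(object$layout, "n_levels")
  pad <- attr(object$layout, "inner_radius") /
    (1 - attr(object$layout, "inner_radius")) * n_levels
  wedge <- attr(object$layout, "wedge")
  w_half <- wedge[["extent"]] / 2
  wedge_dat <- tibble(
    xmin = c(360 - w_half, 0), xmax = c(360, w_half),
    colour = c(palette$key_max, palette$key_min))
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_deg, xmax = .data$start_deg + .data$extent_deg,
      ymin = .data$level - 1 + pad, ymax = .data$level + pad,
      fill = .data$colour)) +
    ggplot2::geom_rect(data = wedge_dat, ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax, ymin = pad, ymax = n_levels + pad,
      fill = .data$colour)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_x_continuous(limits = c(0, 360)) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::theme_void()
}

#' @rdname autoplot.dhm
#' @param x a `dhm`.
#' @method plot dhm
#' @export
plot.dhm <- function(x, ...) print(autoplot(x, ...))

#' Run the simulate / cluster / render pipeline from a YAML config
#'
#' The config has up to three blocks. `simulate`: `kind`
#' (`lineage`/`growth`), `seed`, and the simulator arguments (`n_seqs`,
#' `length`, `iterations`/`generations`, `evening` = `final`/`every`/`none`,
#' `threshold`); alternatively a top-level `fasta` entry names an input file.
#' `cluster`: `method`, `cutoff_lo`, `cutoff_hi`, `step`, optional
#' `group_map`, optional `snapshot` (which snapshot to analyse; default the
#' last). `render`: `wedge_deg`, `width_by`, `svg_out`, `circos_out`,
#' `ladder_out`. Paths are resolved relative to the working directory.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return The `dhm` object, invisibly.
#' @export
dhm_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read config files")
    }
    config <- yaml::yaml.load_file(config)
  }
  sim <- config$simulate
  if (!is.null(config$fasta)) {
    records <- read_fasta(config$fasta)
  } else {
    if (is.null(sim)) abort("config needs a 'simulate' block or a 'fasta' entry")
    seed <- sim$seed %||% 1L
    if (identical(sim$kind, "growth")) {
      policy <- evening_policy(
        "fractional", sim$threshold %||% 0.05,
        check_at = sim$evening %||% "final")
      gs <- simulate_population_growth(
        length = sim$length %||% 100L,
        generations = sim$generations %||% 15L,
        policy = policy, seed = seed)
    } else {
      policy <- evening_policy(
        "absolute", sim$threshold %||% 20L,
        check_at = sim$evening %||% "final")
      gs <- simulate_mutation_lineage(
        n_seqs = sim$n_seqs %||% 100L, length = sim$length %||% 100L,
        iterations = sim$iterations %||% 15L, policy = policy, seed = seed)
    }
    if (!is.null(sim$out_prefix)) {
      write_generation_set(gs, dirname(sim$out_prefix),
                           basename(sim$out_prefix))
    }
    snap <- config$cluster$snapshot %||% (length(gs$snapshots) - 1L)
    records <- gs$snapshots[[snap + 1L]]
  }
  cl <- config$cluster
  cutoffs <- cutoff_ladder(cl$cutoff_lo %||% 0.75, cl$cutoff_hi %||% 1.0,
                           cl$step %||% 0.01)
  gmap <- if (!is.null(cl$group_map)) read_group_map(cl$group_map)
  rd <- config$render
  d <- dhm_build(records, method = cl$method %||% "centroid",
                 cutoffs = cutoffs,
                 wedge_deg = rd$wedge_deg %||% 12,
                 width_by = rd$width_by %||% "abundance",
                 group_map = gmap)
  if (!is.null(cl$ladder_out)) write_ladder_tsv(d$ladder, cl$ladder_out)
  if (!is.null(rd$svg_out)) dhm_render_svg(d, rd$svg_out)
  if (!is.null(rd$circos_out)) dhm_export_circos(d, rd$circos_out)
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
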