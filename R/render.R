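#' Rendering configuration
#'
#' @param canvas canvas width/height in pixels (square).
#' @param inner_radius inner hole radius as a fraction of the outer radius.
#' @param min_stroke minimum stroke width in pixels applied (at render time
#'   only) to sectors too thin to be visible; the stored geometry stays
#'   exact.
#' @param margin fraction of the canvas left as margin.
#' @return A `render_config` list.
#' @export
render_config <- function(canvas = 800, inner_radius = 0.15,
                          min_stroke = 0.25, margin = 0.02) {
  stopifnot(canvas > 0, inner_radius > 0, inner_radius < 1,
            min_stroke >= 0, margin >= 0, margin < 0.5)
  structure(list(canvas = canvas, inner_radius = inner_radius,
                 min_stroke = min_stroke, margin = margin),
            class = "render_config")
}

# angles run clockwise from 12 o'clock; vectorized over sectors
polar_x <- function(cx, r, deg) cx + r * sin(deg * pi / 180)
polar_y <- function(cy, r, deg) cy - r * cos(deg * pi / 180)

sector_path <- function(cx, cy, r0, r1, start, extent) {
  end <- start + extent
  large <- ifelse(extent > 180, 1L, 0L)
  sprintf(paste0("M %.4f %.4f A %.4f %.4f 0 %d 1 %.4f %.4f ",
                 "L %.4f %.4f A %.4f %.4f 0 %d 0 %.4f %.4f Z"),
          polar_x(cx, r1, start), polar_y(cy, r1, start), r1, r1, large,
          polar_x(cx, r1, end), polar_y(cy, r1, end),
          polar_x(cx, r0, end), polar_y(cy, r0, end), r0, r0, large,
          polar_x(cx, r0, start), polar_y(cy, r0, start))
}

#' Render a dendritic heat map layout as SVG
#'
#' Draws one annular sector per (ring, cluster) at its angular span, rings
#' inner to outer by ascending cutoff, plus the key wedge at 0 degrees whose
#' two angular halves show the darkest extreme colours (left half: deepest
#' red, the +scale end toward group 1; right half: deepest blue). Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param layout a [build_layout()] result.
#' @param colours tibble `level`, `cluster_id`, `colour` covering every
#'   laid-out cluster.
#' @param path output file.
#' @param config a [render_config()].
#' @param key_colours length-2 colour vector for the wedge (red extreme,
#'   blue extreme); defaults from [dhm_palette()].
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, colours, path, config = render_config(),
                       key_colours = NULL) {
  stopifnot(inherits(layout, "dhm_layout"), inherits(config, "render_config"))
  if (is.null(key_colours)) {
    pal <- dhm_palette()
    key_colours <- c(pal$key_max, pal$key_min)
  }
  key <- paste(layout$level, layout$cluster_id)
  have <- paste(colours$level, colours$cluster_id)
  idx <- match(key, have)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    abort(sprintf("no colour for cluster %d at level %d",
                  layout$cluster_id[miss], layout$level[miss]))
  }
  fill <- colours$colour[idx]

  n_levels <- attr(layout, "n_levels")
  wedge <- attr(layout, "wedge")
  cx <- config$canvas / 2
  cy <- config$canvas / 2
  r_out <- config$canvas / 2 * (1 - config$margin)
  r_in <- r_out * config$inner_radius
  thick <- (r_out - r_in) / n_levels
  radius0 <- function(level) r_in + (level - 1) * thick
  mid_r <- radius0(layout$level) + thick / 2
  thin <- layout$extent_deg * pi / 180 * mid_r < config$min_stroke

  paths <- sprintf(
    '<path d="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
    sector_path(cx, cy, radius0(layout$level), radius0(layout$level) + thick,
                layout$start_deg, layout$extent_deg),
    fill,
    ifelse(thin, fill, "none"),
    ifelse(thin, format(config$min_stroke), "0"))

  w_start <- wedge[["start"]]
  w_half <- wedge[["extent"]] / 2
  wedge_paths <- c(
    sprintf('<path d="%s" fill="%s" stroke="none" stroke-width="0"/>',
            sector_path(cx, cy, r_in, r_out, w_start, w_half),
            key_colours[1]),
    sprintf('<path d="%s" fill="%s" stroke="none" stroke-width="0"/>',
            sector_path(cx, cy, r_in, r_out, 0, w_half),
            key_colours[2]))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%g" ',
                   'height="%g" viewBox="0 0 %g %g">'),
            config$canvas, config$canvas, config$canvas, config$canvas),
    sprintf('<rect width="%g" height="%g" fill="#FFFFFF"/>',
            config$canvas, config$canvas),
    paths,
    wedge_paths,
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

base_segment_of <- function(layout) {
  # walk parent links down to the base ring
  seg <- integer(nrow(layout))
  base <- layout[layout$level == 1, ]
  lookup <- list()
  for (l in sort(unique(layout$level))) {
    ring <- layout[layout$level == l, ]
    if (l == 1) {
      lookup[[l]] <- setNames(ring$cluster_id, ring$cluster_id)
    } else {
      lookup[[l]] <- setNames(lookup[[l - 1]][as.character(ring$parent_id)],
                              ring$cluster_id)
    }
    seg[layout$level == l] <-
      lookup[[l]][as.character(ring$cluster_id)]
  }
  seg
}

#' Export Circos-ready karyotype, heat-map tracks and configuration template
#'
#' Writes (a) `karyotype.txt` with one segment per base-ring cluster sized by
#' its weight, (b) one 4-column `track_L<level>.txt` per ring with
#' `segment start end value` lines in base-ring coordinate units (each
#' cluster's span mapped into its base-ring ancestor's interval), and (c) a
#' `circos.conf` template referencing the tracks. Circos itself is never
#' invoked.
#'
#' @param layout a [build_layout()] result.
#' @param responses a [bin_responses()] tibble (values written to tracks).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_circos <- function(layout, responses, out_dir) {
  stopifnot(inherits(layout, "dhm_layout"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- layout[layout$level == 1, ]
  scale <- 1000 # coordinate units per weight unit keeps positions integral
  kar <- sprintf("chr - seg%d %d 0 %d grey", base$cluster_id,
                 base$cluster_id, as.integer(round(base$weight * scale)))
  writeLines(kar, file.path(out_dir, "karyotype.txt"))

  seg <- base_segment_of(layout)
  rkey <- paste(responses$level, responses$cluster_id)
  levels <- sort(unique(layout$level))
  track_files <- character(length(levels))
  for (l in levels) {
    sel <- layout$level == l
    ring <- layout[sel, ]
    bseg <- seg[sel]
    b <- base[match(bseg, base$cluster_id), ]
    # position within the ancestor segment, proportional to angle
    rel0 <- (ring$start_deg - b$start_deg) / b$extent_deg
    rel1 <- (ring$start_deg + ring$extent_deg - b$start_deg) / b$extent_deg
    start <- round(rel0 * b$weight * scale)
    end <- round(rel1 * b$weight * scale)
    val <- responses$r[match(paste(l, ring$cluster_id), rkey)]
    track_files[match(l, levels)] <- sprintf("track_L%02d.txt", l)
    writeLines(sprintf("seg%d %d %d %.6g", bseg, as.integer(start),
                       as.integer(end), val),
               file.path(out_dir, track_files[match(l, levels)]))
  }

  n <- length(levels)
  r0 <- attr(layout, "inner_radius")
  radii <- r0 + (seq_len(n) - 1) / n * (0.98 - r0)
  plots <- sprintf(
    "<plot>\ntype = heatmap\nfile = %s\nr0 = %.4fr\nr1 = %.4fr\ncolor = blues-11-seq,white,reds-11-seq\n</plot>",
    track_files, radii, radii + (0.98 - r0) / n)
  conf <- c("# Circos configuration template for a dendritic heat map",
            "karyotype = karyotype.txt",
            "<ideogram>", "thickness = 2p", "show_label = no",
            "<spacing>", "default = 0.002r", "</spacing>", "</ideogram>",
            "<plots>", plots, "</plots>",
            "<image>", "<<include etc/image.conf>>", "</image>",
            "<<include etc/colors_fonts_patterns.conf>>",
            "<<include etc/housekeeping.conf>>")
  writeLines(conf, file.path(out_dir, "circos.conf"))
  invisible(out_dir)
}
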