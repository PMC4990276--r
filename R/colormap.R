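#' Log-ratio relative-abundance bin response
#'
#' A cluster's heat map value is `log10((g1 + 1) / (g2 + 1))` of its two
#' group abundances. The +1 smoothing keeps the ratio finite for empty
#' groups; the log puts large and small clusters on a comparable scale, and
#' the value is antisymmetric under swapping the groups. Base 10 is used
#' so exported values read naturally; colour categories depend only on the
#' ratio of a response to the global scale, so the base does not affect the
#' rendered map.
#'
#' @param g1,g2 non-negative group abundances (vectorized).
#' @return `log10((g1 + 1) / (g2 + 1))`; positive toward group 1.
#' @examples
#' bin_response(9, 0) # 1
#' @export
bin_response <- function(g1, g2) {
  if (any(g1 < 0) || any(g2 < 0)) abort("group counts must be non-negative")
  log10((g1 + 1) / (g2 + 1))
}

#' Global symmetric normalization scale
#'
#' The scale M is the maximum absolute bin response over all supplied
#' responses. When several heat map panels are displayed together, supply all
#' their responses (as a list) so every panel shares one scale and hues are
#' comparable between panels; the key wedge displays the -M and +M extremes.
#'
#' @param responses numeric vector of bin responses, or a list of such
#'   vectors (one per panel).
#' @return A non-negative number; 0 when every response is neutral.
#' @export
normalization_scale <- function(responses) {
  r <- unlist(responses, use.names = FALSE)
  if (length(r) == 0) abort("no responses supplied")
  max(abs(r))
}

#' Colour category of a bin response
#'
#' Maps a response to one of 23 categories: 0 (white) exactly when the
#' response is 0 (or the scale is degenerate), otherwise
#' `sign(r) * min(11, floor(|r| / M * 11) + 1)`, so categories are odd in r,
#' monotone in |r|, and |r| = M maps to the darkest +/-11. Only an exactly
#' neutral response is white (bin edges are half-open lower bounds).
#'
#' @param r bin response(s).
#' @param M non-negative scale covering all responses (`|r| <= M`).
#' @return Integer categories in `[-11, 11]`.
#' @export
category_of <- function(r, M) {
  stopifnot(length(M) == 1, M >= 0)
  if (any(abs(r) > M + 1e-12)) {
    abort("|r| exceeds the normalization scale M; recompute M over all panels")
  }
  if (M == 0) return(rep(0L, length(r)))
  k <- as.integer(sign(r)) * pmin(11L, floor(pmin(abs(r), M) / M * 11) + 1L)
  k[r == 0] <- 0L
  as.integer(k)
}

#' Diverging 23-colour palette
#'
#' Two 11-step sequential ramps (light to dark) plus white: reds for group 1
#' excess, blues for group 2 excess. The default ramps interpolate linearly
#' in RGB from near-white to dark Brewer-inspired endpoints; all 23 colours
#' are distinct. `key_min`/`key_max` are the colours of categories -11/+11,
#' shown in the key wedge.
#'
#' @param red_dark,blue_dark dark endpoints (category +/-11).
#' @param red_light,blue_light near-white ramp starts (category +/-1).
#' @param neutral the category-0 colour.
#' @return A `dhm_palette`: list with `reds`, `blues` (each 11 colours,
#'   light to dark), `neutral`, `key_min`, `key_max`.
#' @export
dhm_palette <- function(red_dark = "#67001F", blue_dark = "#053061",
                        red_light = "#FFF0EB", blue_light = "#EBF4FB",
                        neutral = "#FFFFFF") {
  reds <- grDevices::colorRampPalette(c(red_light, red_dark),
                                      space = "rgb")(11)
  blues <- grDevices::colorRampPalette(c(blue_light, blue_dark),
                                       space = "rgb")(11)
  pal <- structure(
    list(reds = reds, blues = blues, neutral = neutral,
         key_min = blues[11], key_max = reds[11]),
    class = "dhm_palette"
  )
  if (length(unique(c(pal$reds, pal$blues, pal$neutral))) != 23) {
    abort("palette colours are not 23 distinct values")
  }
  pal
}

#' @export
print.dhm_palette <- function(x, ...) {
  cat("<dhm_palette> 23 colours: reds", x$reds[1], "..", x$reds[11],
      "| white | blues", x$blues[1], "..", x$blues[11], "\n")
  invisible(x)
}

#' Colour of a category
#'
#' Category 0 maps to the neutral white; +k to the k-th red (light to dark);
#' -k to the k-th blue.
#'
#' @param category integer categories in `[-11, 11]` (vectorized).
#' @param palette a [dhm_palette()].
#' @return Hex colour strings.
#' @export
color_of <- function(category, palette = dhm_palette()) {
  stopifnot(inherits(palette, "dhm_palette"))
  if (any(is.na(category)) || any(category < -11) || any(category > 11) ||
      any(category != floor(category))) {
    abort("categories must be integers in [-11, 11]")
  }
  out <- rep(palette$neutral, length(category))
  pos <- category > 0
  neg <- category < 0
  out[pos] <- palette$reds[category[pos]]
  out[neg] <- palette$blues[-category[neg]]
  out
}

#' Per-cluster bin responses of a ladder
#'
#' @param ladder a `cluster_ladder`.
#' @return A tibble `level`, `cluster_id`, `g1`, `g2`, `r`.
#' @export
bin_responses <- function(ladder) {
  stopifnot(inherits(ladder, "cluster_ladder"))
  rings <- ladder$rings
  tibble(level = rings$level, cluster_id = rings$cluster_id,
         g1 = rings$g1, g2 = rings$g2,
         r = bin_response(rings$g1, rings$g2))
}

#' Export per-cluster responses as TSV
#'
#' Rows are `level<TAB>cluster_id<TAB>g1<TAB>g2<TAB>r<TAB>category`.
#'
#' @param responses a [bin_responses()] tibble.
#' @param M normalization scale (default: panel-local maximum |r|).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses_tsv <- function(responses, path,
                                M = normalization_scale(responses$r)) {
  cat_col <- category_of(responses$r, M)
  lines <- c("level\tcluster_id\tg1\tg2\tr\tcategory",
             sprintf("%d\t%d\t%g\t%g\t%.6g\t%d", responses$level,
                     responses$cluster_id, responses$g1, responses$g2,
                     responses$r, cat_col))
  writeLines(lines, path)
  invisible(path)
}
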