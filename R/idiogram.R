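#' Idiogram layout of a haploid complement
#'
#' Orders chromosome pairs by decreasing total length and computes, for
#' each, the centromere position as a fraction of chromosome length from
#' the top (the short arm is drawn above the centromere, so the offset
#' equals the centromeric index). Ties in total length are broken by the
#' higher centromeric index, then by `pair_id`.
#'
#' @param x a `karyotype` object or a metrics data frame with columns
#'   `pair_id`, `long_arm`, `short_arm`, `total_len`,
#'   `centromeric_index`, `morph_class`.
#' @param normalize if `TRUE` (default) heights are scaled so the largest
#'   chromosome has unit height.
#' @return A data frame of class `idiogram_layout` with columns
#'   `slot` (1-based x position), `pair_id`, `long_arm`, `short_arm`,
#'   `height` (possibly normalized), `centromere_offset`, `morph_class`.
#' @export
idiogram_layout <- function(x, normalize = TRUE) {
  m <- if (inherits(x, "karyotype")) x$metrics else x
  req <- c("pair_id", "long_arm", "short_arm", "total_len",
           "centromeric_index", "morph_class")
  if (!is.data.frame(m) || nrow(m) == 0L || !all(req %in% names(m)))
    stop("x must be a karyotype or a nonempty metrics data frame")
  ord <- order(-m$total_len, -m$centromeric_index, m$pair_id)
  m <- m[ord, , drop = FALSE]
  scale <- if (normalize) max(m$total_len) else 1
  out <- data.frame(
    slot = seq_len(nrow(m)),
    pair_id = m$pair_id,
    long_arm = m$long_arm,
    short_arm = m$short_arm,
    height = m$total_len / scale,
    centromere_offset = m$centromeric_index,
    morph_class = m$morph_class
  )
  class(out) <- c("idiogram_layout", class(out))
  out
}

idiogram_default_style <- function() {
  list(
    glyph_width = 14,       # px
    slot_spacing = 26,      # px between slot centers
    max_height = 260,       # px height of the tallest chromosome
    margin = 30,            # px outer margin
    centromere_gap = 3,     # px half-gap at the centromere
    colors = c(m = "#4477aa", sm = "#66ccee", st = "#ccbb44", t = "#ee6677"),
    label_size = 9,         # px font size of pair labels
    diploid = FALSE         # draw two glyphs per pair
  )
}

#' Render an idiogram as SVG
#'
#' Draws one glyph per chromosome pair (haploid representation; set the
#' style option `diploid = TRUE` for two side-by-side glyphs per pair):
#' two stacked arm blocks separated by a centromere mark, colored and
#' annotated by morphology class. The output is a deterministic function
#' of the layout and style, so repeated renders are byte-identical.
#'
#' @param layout an `idiogram_layout`.
#' @param file optional path; when given the SVG text is also written
#'   there.
#' @param style named list overriding entries of the default style
#'   (glyph width/spacing/height in px, per-class `colors`, `diploid`).
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
idiogram_svg <- function(layout, file = NULL, style = list()) {
  if (!inherits(layout, "idiogram_layout")) stop("layout must be an idiogram_layout")
  if (any(layout$long_arm <= 0) || any(layout$short_arm <= 0))
    stop("cannot render zero-length arms")
  sty <- utils::modifyList(idiogram_default_style(), style)
  per_slot <- if (isTRUE(sty$diploid)) 2L else 1L
  n <- nrow(layout)
  width <- 2 * sty$margin + n * sty$slot_spacing * per_slot
  height <- 2 * sty$margin + sty$max_height + 20
  unit <- sty$max_height / max(layout$height)
  fmt <- function(x) formatC(x, format = "fg", digits = 7)
  rects <- character(0)
  for (i in seq_len(n)) {
    row <- layout[i, ]
    h <- row$height * unit
    h_short <- h * row$centromere_offset
    h_long <- h - h_short
    col <- sty$colors[[as.character(row$morph_class)]]
    for (k in seq_len(per_slot)) {
      x0 <- sty$margin + ((i - 1) * per_slot + k - 1) * sty$slot_spacing
      y_top <- sty$margin + (sty$max_height - h)
      y_cen <- y_top + h_short
      rects <- c(rects,
        sprintf('<g class="pair" data-pair="%s" data-class="%s">', row$pair_id, row$morph_class),
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="black" stroke-width="0.8"/>',
                fmt(x0), fmt(y_top), fmt(sty$glyph_width),
                fmt(max(h_short - sty$centromere_gap, 0.5)), col),
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="black" stroke-width="0.8"/>',
                fmt(x0), fmt(y_cen + sty$centromere_gap), fmt(sty$glyph_width),
                fmt(max(h_long - sty$centromere_gap, 0.5)), col),
        sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1.2"/>',
                fmt(x0 - 2), fmt(y_cen), fmt(x0 + sty$glyph_width + 2), fmt(y_cen)),
        if (k == 1L) sprintf(
          '<text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
          fmt(x0 + sty$glyph_width / 2), fmt(sty$margin + sty$max_height + 14),
          fmt(sty$label_size), row$pair_id),
        '</g>')
    }
  }
  svg <- paste(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(width), fmt(height), fmt(width), fmt(height)),
    '<rect width="100%" height="100%" fill="white"/>',
    rects,
    '</svg>'), collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}

#' Plot method: draw the idiogram with base graphics
#'
#' @param x a `karyotype` object.
#' @param ... passed to [idiogram_layout()] (`normalize`).
#' @export
plot.karyotype <- function(x, ...) {
  lay <- idiogram_layout(x, ...)
  cols <- idiogram_default_style()$colors
  n <- nrow(lay)
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(-0.08, 1.05),
                 xlab = "chromosome pair", ylab = "relative length",
                 axes = FALSE, main = paste0(x$species_label, "  (", x$formula,
                                             ", NF=", x$fundamental_number, ")"))
  graphics::axis(1, at = seq_len(n), labels = lay$pair_id, cex.axis = 0.6)
  graphics::axis(2)
  w <- 0.3
  for (i in seq_len(n)) {
    h <- lay$height[i]
    y_cen <- h * (1 - lay$centromere_offset[i])  # centromere height from baseline
    col <- cols[[as.character(lay$morph_class[i])]]
    graphics::rect(i - w, 0, i + w, y_cen - 0.004, col = col, border = "black")
    graphics::rect(i - w, y_cen + 0.004, i + w, h, col = col, border = "black")
    graphics::segments(i - w - 0.1, y_cen, i + w + 0.1, y_cen, lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), fill = unname(unlist(cols)),
                   bty = "n", cex = 0.8)
  invisible(lay)
}
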