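# Idiogram rendering: one vertical bar per chromosome scaled to bp, one
# colored mark per called locus at its bin midpoint, written as a
# self-contained SVG plus a TSV twin of the plotted marks so the geometry
# is queryable without parsing the drawing.

.DEFAULT_PALETTE <- c("#D62728", "#2CA02C", "#1F77B4", "#FF7F0E", "#9467BD",
                      "#8C564B", "#E377C2", "#17BECF", "#BCBD22", "#7F7F7F",
                      "#AEC7E8", "#98DF8A")

#' Render an idiogram of called loci
#'
#' Draws one vertical chromosome bar per entry of `chrom_lengths`, scaled
#' so the longest chromosome spans the full drawing height, and one
#' colored mark per locus at the vertical position of its bin midpoint.
#' Colors come from `channel_colors` (a named vector, `probe_id -> color`)
#' or a fixed palette in probe order. The drawing is a self-contained SVG;
#' a TSV of plotted marks (probe, chromosome, midpoint, pixel geometry) is
#' written alongside. Layout is deterministic.
#'
#' @param loci Locus data frame from [bin_and_call()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param channel_colors Optional named vector mapping probe ids to colors.
#' @param svg_path Output SVG path.
#' @param marks_path Output marks TSV path (default: `svg_path` with
#'   `_marks.tsv`).
#' @return Invisibly, a list with `svg`, `marks_path` and the `marks` data
#'   frame (`probe_id, chrom, bin_mid, chrom_length, x, y, bar_top,
#'   bar_height, color`).
#' @export
render_idiogram <- function(loci, chrom_lengths, channel_colors = NULL,
                            svg_path, marks_path = NULL) {
  stopifnot(length(chrom_lengths) > 0L, all(chrom_lengths > 0))
  if (nrow(loci) > 0L) {
    unknown <- setdiff(loci$chrom, names(chrom_lengths))
    if (length(unknown) > 0L)
      stop("loci on unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(marks_path))
    marks_path <- sub("\\.svg$", "_marks.tsv", svg_path)

  probes <- unique(loci$probe_id)
  if (is.null(channel_colors)) {
    channel_colors <- stats::setNames(
      rep_len(.DEFAULT_PALETTE, max(1L, length(probes))), probes)
  }

  margin <- 40; bar_w <- 22; gap <- 58; plot_h <- 400
  n_chr <- length(chrom_lengths)
  width <- margin * 2 + n_chr * bar_w + (n_chr - 1) * gap + 140  # legend room
  height <- margin * 2 + plot_h + 20
  maxlen <- max(chrom_lengths)

  bar_x <- margin + (seq_len(n_chr) - 1L) * (bar_w + gap)
  bar_h <- plot_h * chrom_lengths / maxlen
  bar_top <- rep(margin, n_chr)
  names(bar_x) <- names(bar_h) <- names(bar_top) <- names(chrom_lengths)

  svg <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" ',
           'viewBox="0 0 %g %g">'), width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>')
  for (i in seq_len(n_chr)) {
    svg <- c(svg, sprintf(
      '<rect class="chrom" x="%g" y="%g" width="%g" height="%g" rx="10" fill="#F2F2F2" stroke="#444444"/>',
      bar_x[i], bar_top[i], bar_w, bar_h[i]))
    svg <- c(svg, sprintf(
      '<text x="%g" y="%g" font-size="12" text-anchor="middle" font-family="sans-serif">%s</text>',
      bar_x[i] + bar_w / 2, bar_top[i] + bar_h[i] + 16,
      names(chrom_lengths)[i]))
  }

  marks <- data.frame(probe_id = character(), chrom = character(),
                      bin_mid = numeric(), chrom_length = numeric(),
                      x = numeric(), y = numeric(), bar_top = numeric(),
                      bar_height = numeric(), color = character(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) > 0L) {
    mid <- (loci$bin_start + loci$bin_end) / 2
    len <- chrom_lengths[loci$chrom]
    y <- bar_top[loci$chrom] + bar_h[loci$chrom] * mid / len
    x <- bar_x[loci$chrom] + bar_w / 2
    col <- unname(channel_colors[loci$probe_id])
    col[is.na(col)] <- "#000000"
    marks <- data.frame(probe_id = loci$probe_id, chrom = loci$chrom,
                        bin_mid = mid, chrom_length = unname(len),
                        x = unname(x), y = unname(y),
                        bar_top = unname(bar_top[loci$chrom]),
                        bar_height = unname(bar_h[loci$chrom]),
                        color = col, stringsAsFactors = FALSE)
    svg <- c(svg, sprintf(
      '<rect class="mark" x="%g" y="%g" width="%g" height="3" fill="%s"/>',
      marks$x - bar_w / 2, marks$y - 1.5, bar_w, marks$color))
  }

  lx <- margin + n_chr * bar_w + (n_chr - 1) * gap + 30
  for (i in seq_along(probes)) {
    svg <- c(svg, sprintf(
      '<rect x="%g" y="%g" width="12" height="12" fill="%s"/>',
      lx, margin + (i - 1) * 18, channel_colors[probes[i]]))
    svg <- c(svg, sprintf(
      '<text x="%g" y="%g" font-size="12" font-family="sans-serif">%s</text>',
      lx + 16, margin + (i - 1) * 18 + 10, probes[i]))
  }
  svg <- c(svg, "</svg>")
  writeLines(svg, svg_path)
  utils::write.table(marks, marks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(svg = svg_path, marks_path = marks_path, marks = marks))
}
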