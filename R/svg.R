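# stable bundle color: golden-ratio hue permutation so reruns and
# cross-sample comparisons keep per-bundle colors
bundle_color <- function(bundle_id) {
  h <- (bundle_id * 0.61803398874989) %% 1
  grDevices::hsv(h, 0.65, 0.88)
}

fmt <- function(x) sprintf("%.2f", x)

#' Render a principal-bundle decomposition as SVG
#'
#' One horizontal track per contig; segments are drawn as direction arrows
#' colored deterministically by bundle id, with gray gaps left where the
#' contig is not assigned to any bundle.  Repeat-flagged (`R`) segments are
#' outlined with `stroke_width * highlight_repeats`.  An optional left
#' dendrogram panel (from a `.ddg` layout file) orders the tracks, and an
#' optional annotation file (`contig<TAB>text`) adds per-track labels.
#' Output is deterministic: the same BED and configuration yield identical
#' bytes.
#'
#' @param bed path to a bundle BED file or a segment data.frame.
#' @param path output SVG file.
#' @param track_range bases shown per track (default: max segment end).
#' @param track_tick_interval axis tick spacing in bases.
#' @param track_panel_width width of the track panel in drawing units.
#' @param stroke_width segment outline width.
#' @param annotations optional annotation file path.
#' @param ddg_file optional dendrogram layout file from
#'   [writeDistanceFiles()].
#' @param highlight_repeats stroke emphasis factor for `R`-flagged
#'   segments.
#' @return `path`, invisibly.
#' @export
renderBundleSVG <- function(bed, path, track_range = NULL,
                            track_tick_interval = NULL,
                            track_panel_width = 1200, stroke_width = 0.5,
                            annotations = NULL, ddg_file = NULL,
                            highlight_repeats = 3) {
  segments <- if (is.character(bed)) readBundleBed(bed) else bed
  if (is(segments, "BundleDecomposition")) segments <- segments@segments
  if (is.null(track_range)) track_range <- max(segments$end, 1L)
  if (track_range <= 0) stopf("track_range must be > 0")
  if (is.null(track_tick_interval))
    track_tick_interval <- max(1, 10^floor(log10(track_range)))
  if (track_tick_interval > track_range)
    stopf("track_tick_interval must not exceed track_range")
  contigs <- unique(segments$contig_name)
  ddg <- NULL
  if (!is.null(ddg_file)) {
    ddg <- readDendrogramLayout(ddg_file)
    ord <- ddg$leaves$name[order(ddg$leaves$y)]
    contigs <- c(intersect(ord, contigs), setdiff(contigs, ord))
  }
  ann <- NULL
  if (!is.null(annotations)) {
    al <- strsplit(readLines(annotations), "\t", fixed = TRUE)
    al <- al[vapply(al, length, 1L) >= 2L]
    ann <- stats::setNames(vapply(al, `[`, "", 2L), vapply(al, `[`, "", 1L))
  }
  ddg_w <- if (is.null(ddg)) 0 else 160
  label_w <- 170
  track_h <- 22; pad <- 10; axis_h <- 26
  W <- ddg_w + label_w + track_panel_width + 2 * pad
  H <- length(contigs) * track_h + axis_h + 2 * pad
  xscale <- track_panel_width / track_range
  x0 <- ddg_w + label_w + pad
  out <- c(sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%s" height="%s" viewBox="0 0 %s %s">'),
    fmt(W), fmt(H), fmt(W), fmt(H)),
    '<rect width="100%" height="100%" fill="white"/>')
  y_of <- stats::setNames(pad + (seq_along(contigs) - 1L) * track_h + track_h / 2,
                          contigs)
  # dendrogram panel
  if (!is.null(ddg) && nrow(ddg$merges)) {
    maxh <- max(ddg$merges$height, 1e-9)
    hx <- function(h) ddg_w - 6 - (h / maxh) * (ddg_w - 14)
    leaf_row <- function(nm) if (nm %in% names(y_of)) y_of[[nm]] else NA
    pos <- list()
    for (i in seq_len(nrow(ddg$leaves)))
      pos[[sprintf("L%d", ddg$leaves$index[i])]] <-
        c(hx(0), leaf_row(ddg$leaves$name[i]))
    for (i in seq_len(nrow(ddg$merges))) {
      m <- ddg$merges[i, ]
      a <- pos[[m$child_a]]; b <- pos[[m$child_b]]
      if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) next
      x <- hx(m$height); y <- (a[2] + b[2]) / 2
      out <- c(out, sprintf(
        '<polyline points="%s,%s %s,%s %s,%s %s,%s" fill="none" stroke="black" stroke-width="0.8"/>',
        fmt(a[1]), fmt(a[2]), fmt(x), fmt(a[2]), fmt(x), fmt(b[2]),
        fmt(b[1]), fmt(b[2])))
      pos[[sprintf("M%d", m$id)]] <- c(x, y)
    }
  }
  # axis
  ax_y <- pad + length(contigs) * track_h + 12
  out <- c(out, sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
    fmt(x0), fmt(ax_y), fmt(x0 + track_panel_width), fmt(ax_y)))
  for (tick in seq(0, track_range, by = track_tick_interval)) {
    tx <- x0 + tick * xscale
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
      fmt(tx), fmt(ax_y), fmt(tx), fmt(ax_y + 4)),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle">%d</text>',
              fmt(tx), fmt(ax_y + 14), as.integer(tick)))
  }
  # tracks
  for (cn in contigs) {
    y <- y_of[[cn]]
    lab <- cn
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="start" class="track-label">%s</text>',
      fmt(ddg_w + 4), fmt(y + 3), lab))
    if (!is.null(ann) && cn %in% names(ann))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="8" fill="#555555" text-anchor="start" class="annotation">%s</text>',
        fmt(ddg_w + 4), fmt(y + 11), ann[[cn]]))
    # gray backbone for unassigned spans
    cs <- segments[segments$contig_name == cn, , drop = FALSE]
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#bbbbbb" stroke-width="2"/>',
      fmt(x0), fmt(y), fmt(x0 + min(max(cs$end), track_range) * xscale),
      fmt(y)))
    h2 <- 6
    for (i in seq_len(nrow(cs))) {
      b <- max(0, cs$begin[i]); e <- min(track_range, cs$end[i])
      if (e <= b) next
      xa <- x0 + b * xscale; xb <- x0 + e * xscale
      head_len <- min(6, (xb - xa) / 2)
      pts <- if (cs$orientation[i] == 0L)
        sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
                fmt(xa), fmt(y - h2), fmt(xb - head_len), fmt(y - h2),
                fmt(xb), fmt(y), fmt(xb - head_len), fmt(y + h2),
                fmt(xa), fmt(y + h2))
      else
        sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s",
                fmt(xb), fmt(y - h2), fmt(xa + head_len), fmt(y - h2),
                fmt(xa), fmt(y), fmt(xa + head_len), fmt(y + h2),
                fmt(xb), fmt(y + h2))
      sw <- if (cs$repeat_flag[i] == "R")
        stroke_width * highlight_repeats else stroke_width
      out <- c(out, sprintf(
        '<polygon class="arrow" points="%s" fill="%s" stroke="black" stroke-width="%s"/>',
        pts, bundle_color(cs$bundle_id[i]), fmt(sw)))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
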