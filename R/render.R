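# Drawing. A RoguePlot is a rectangular phylogram of the consensus in which
# every branch parallel to the tree direction is coloured by the probability
# of the rogue attaching directly to that branch, and every perpendicular
# connector is coloured by the probability of attachment to some branch absent
# from the consensus whose MRCA is that node. SVG is the reference output:
# plain text, byte-identical across repeated calls.

#' Style options for a RoguePlot
#'
#' @param palette two colours defining the probability ramp (probability 0 is
#'   never drawn from the ramp, see `zero_colour`).
#' @param zero_colour line colour for branches/connectors with zero attachment
#'   probability, so the tree structure stays visible.
#' @param show_labels draw numeric probability labels above segments?
#' @param label_threshold smallest probability that receives a numeric label.
#' @param width canvas width in pixels.
#' @param row_height vertical space per tip in pixels.
#' @param line_width stroke width for branches.
#' @param legend draw the probability colour legend?
#' @return an object of class `rogueplot_style`.
#' @export
rogueplot_style <- function(palette = c("#FFFFFF", "#7F0000"),
                            zero_colour = "#AAAAAA",
                            show_labels = TRUE,
                            label_threshold = 0.05,
                            width = 760,
                            row_height = 18,
                            line_width = 2,
                            legend = TRUE) {
  stopifnot(length(palette) >= 2L, label_threshold >= 0, label_threshold <= 1)
  structure(list(palette = palette, zero_colour = zero_colour,
                 show_labels = show_labels, label_threshold = label_threshold,
                 width = width, row_height = row_height,
                 line_width = line_width, legend = legend),
            class = "rogueplot_style")
}

prob_colour <- function(p, style) {
  ramp <- grDevices::colorRamp(style$palette, space = "rgb")
  out <- character(length(p))
  zero <- p <= 0
  out[zero] <- style$zero_colour
  if (any(!zero)) {
    rgb <- ramp(pmin(p[!zero], 1))
    out[!zero] <- sprintf("#%02X%02X%02X", round(rgb[, 1]), round(rgb[, 2]), round(rgb[, 3]))
  }
  out
}

fmt_px <- function(x) sprintf("%.2f", x)

#' Render a RoguePlot as SVG
#'
#' Lays the consensus out as a rectangular cladogram (tips evenly spaced,
#' horizontal position by node depth; unit branch lengths are used when the
#' tree carries none) and writes an SVG 1.1 file. Horizontal segments are
#' coloured by the direct-attachment probability of the branch they represent,
#' vertical connectors by the MRCA-bucket probability of their node; a stub to
#' the left of the root carries the root-attachment probability. Rendering is
#' pure and deterministic: the same inputs produce byte-identical files.
#'
#' @param consensus a rooted `phylo`.
#' @param dist an `attachment_distribution` computed against `consensus`.
#' @param style a [rogueplot_style()].
#' @param out_path path of the SVG file to write.
#' @return `out_path`, invisibly.
#' @export
render_rogueplot <- function(consensus, dist, style = rogueplot_style(), out_path) {
  stopifnot(inherits(dist, "attachment_distribution"), inherits(style, "rogueplot_style"))
  idx <- consensus_index(consensus)
  if (!all(names(dist$direct) %in% idx$keys) || !all(names(dist$mrca) %in% idx$keys)) {
    stop("distribution refers to clades absent from this consensus", call. = FALSE)
  }
  nt <- length(consensus$tip.label)
  nn <- nt + consensus$Nnode
  ch <- tree_children(consensus)
  # canonical tip order: children sorted by smallest descendant label
  minlab <- vapply(idx$tipsets, min, character(1))
  tip_order <- integer(0)
  stack <- root_node(consensus)
  while (length(stack) > 0L) {
    node <- stack[1L]
    stack <- stack[-1L]
    if (node <= nt) {
      tip_order <- c(tip_order, node)
    } else {
      kids <- ch[[node]][order(minlab[ch[[node]]])]
      stack <- c(kids, stack)
    }
  }
  depth <- node_depths(consensus, use_lengths = !is.null(consensus$edge.length))
  ypos <- numeric(nn)
  ypos[tip_order] <- seq_len(nt)
  po <- postorder_edges(consensus)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]
    ypos[p] <- mean(ypos[ch[[p]]])
  }
  # pixel geometry
  margin <- 12
  label_gap <- 6
  char_w <- 7.2
  label_area <- max(nchar(consensus$tip.label)) * char_w + label_gap
  legend_area <- if (style$legend) 70 else 0
  stub <- 0.6
  x_scale <- (style$width - 2 * margin - label_area - legend_area) / (max(depth) + stub)
  px <- function(d) margin + (d + stub) * x_scale
  height <- 2 * margin + (nt + 1) * style$row_height
  py <- function(y) margin + y * style$row_height
  prob_of <- function(map, node) {
    p <- map[idx$keys[node]]
    if (is.na(p)) 0 else as.numeric(p)
  }
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            as.integer(style$width), as.integer(ceiling(height))),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            as.integer(style$width), as.integer(ceiling(height)))
  )
  hline <- function(x1, x2, y, colour, id) {
    sprintf('<line class="branch" id="b%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-linecap="square"/>',
            id, fmt_px(x1), fmt_px(y), fmt_px(x2), fmt_px(y), colour, fmt_px(style$line_width))
  }
  vline <- function(x, y1, y2, colour, id) {
    sprintf('<line class="connector" id="v%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-linecap="square"/>',
            id, fmt_px(x), fmt_px(y1), fmt_px(x), fmt_px(y2), colour, fmt_px(style$line_width))
  }
  labels <- character(0)
  root <- root_node(consensus)
  # one horizontal segment per branch (plus the root stub), parallel = direct
  for (node in seq_len(nn)) {
    p_direct <- prob_of(dist$direct, node)
    if (node == root) {
      svg <- c(svg, hline(px(-stub), px(depth[node]), py(ypos[node]),
                          prob_colour(p_direct, style), node))
    } else {
      svg <- c(svg, hline(px(depth[idx$parent[node]]), px(depth[node]), py(ypos[node]),
                          prob_colour(p_direct, style), node))
    }
    if (style$show_labels && p_direct >= style$label_threshold) {
      xm <- if (node == root) px(depth[node] - stub / 2) else
        px((depth[idx$parent[node]] + depth[node]) / 2)
      labels <- c(labels, sprintf(
        '<text class="prob" x="%s" y="%s" font-size="8" font-family="sans-serif" text-anchor="middle" fill="#000000">%.2f</text>',
        fmt_px(xm), fmt_px(py(ypos[node]) - 3), p_direct))
    }
  }
  # one vertical connector per internal node, perpendicular = mrca
  for (node in (nt + 1L):nn) {
    ys <- ypos[ch[[node]]]
    p_mrca <- prob_of(dist$mrca, node)
    svg <- c(svg, vline(px(depth[node]), py(min(ys)), py(max(ys)),
                        prob_colour(p_mrca, style), node))
    if (style$show_labels && p_mrca >= style$label_threshold) {
      labels <- c(labels, sprintf(
        '<text class="prob" x="%s" y="%s" font-size="8" font-family="sans-serif" text-anchor="start" fill="#000000">%.2f</text>',
        fmt_px(px(depth[node]) + 3), fmt_px(py(ypos[node]) - 3), p_mrca))
    }
  }
  # tip labels
  for (tip in seq_len(nt)) {
    svg <- c(svg, sprintf(
      '<text class="tip" x="%s" y="%s" font-size="10" font-family="sans-serif" fill="#000000">%s</text>',
      fmt_px(px(depth[tip]) + label_gap), fmt_px(py(ypos[tip]) + 3.5),
      xml_escape(consensus$tip.label[tip])))
  }
  svg <- c(svg, labels)
  if (style$legend) {
    lx <- style$width - margin - 50
    steps <- 40
    ly0 <- margin + 10
    bar_h <- 100
    for (i in seq_len(steps)) {
      pv <- (steps - i + 0.5) / steps
      svg <- c(svg, sprintf('<rect x="%s" y="%s" width="12" height="%s" fill="%s"/>',
                            fmt_px(lx), fmt_px(ly0 + (i - 1) * bar_h / steps),
                            fmt_px(bar_h / steps + 0.5), prob_colour(pv, style)))
    }
    svg <- c(svg,
      sprintf('<rect x="%s" y="%s" width="12" height="%s" fill="none" stroke="#000000" stroke-width="0.5"/>',
              fmt_px(lx), fmt_px(ly0), fmt_px(bar_h)),
      sprintf('<text x="%s" y="%s" font-size="8" font-family="sans-serif" fill="#000000">1</text>',
              fmt_px(lx + 16), fmt_px(ly0 + 3)),
      sprintf('<text x="%s" y="%s" font-size="8" font-family="sans-serif" fill="#000000">0.5</text>',
              fmt_px(lx + 16), fmt_px(ly0 + bar_h / 2 + 3)),
      sprintf('<text x="%s" y="%s" font-size="8" font-family="sans-serif" fill="#000000">0</text>',
              fmt_px(lx + 16), fmt_px(ly0 + bar_h + 3)),
      sprintf('<text x="%s" y="%s" font-size="8" font-family="sans-serif" fill="#000000">P(attachment)</text>',
              fmt_px(lx - 4), fmt_px(ly0 + bar_h + 16)))
  }
  svg <- c(svg, "</svg>")
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con, sep = "\n")
  invisible(out_path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export an attachment distribution as a TSV table
#'
#' One row per probability bucket, sorted by descending probability and then
#' lexicographically by clade key, followed by a `TOTAL` row. Probabilities
#' are printed with six decimals and, being integer multiples of
#' `1/n_trees`, re-parse to exact counts.
#'
#' @param dist an `attachment_distribution`.
#' @return a single string of tab-separated lines.
#' @export
export_table <- function(dist) {
  stopifnot(inherits(dist, "attachment_distribution"))
  tab <- attachment_table(dist)
  lines <- c(
    "rogue\tkind\tclade\tcount\tprobability",
    sprintf("%s\t%s\t%s\t%d\t%.6f", tab$rogue, tab$kind, tab$clade, tab$count, tab$probability),
    sprintf("%s\tTOTAL\t\t%d\t%.6f", dist$rogue, sum(tab$count),
            sum(tab$probability))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Attach per-node probability annotations to a consensus tree
#'
#' Adds a `node.comment` vector with one `[&direct=...,mrca=...]` comment per
#' node, for emission through [write_newick()] with
#' `include_annotations = TRUE`.
#'
#' @param consensus a rooted `phylo`.
#' @param dist an `attachment_distribution` computed against `consensus`.
#' @return the consensus with a `node.comment` field.
#' @export
annotate_attachments <- function(consensus, dist) {
  stopifnot(inherits(dist, "attachment_distribution"))
  idx <- consensus_index(consensus)
  nn <- length(consensus$tip.label) + consensus$Nnode
  cm <- character(nn)
  for (node in seq_len(nn)) {
    d <- dist$direct[idx$keys[node]]
    m <- dist$mrca[idx$keys[node]]
    cm[node] <- sprintf("[&direct=%.6f,mrca=%.6f]",
                        if (is.na(d)) 0 else d, if (is.na(m)) 0 else m)
  }
  consensus$node.comment <- cm
  consensus
}
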