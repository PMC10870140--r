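# Tree and comparison-matrix rendering. Figures are conveniences: every
# figure's inputs are also available as plain tables, so no scientific
# result depends on a plotting backend.

#' Render a tree as text or DOT
#'
#' Nodes are labelled with the number of haplotypes sharing their haplotype;
#' an optional tag map (haplotype row label to tag) colours/annotates the
#' haplotypes of tagged samples, e.g. a phenotype or repeat class. Output is
#' deterministic for fixed input.
#'
#' @param hst an `hst`.
#' @param style `"text"` (indented listing) or `"dot"` (Graphviz).
#' @param tags optional named character vector, row label -> tag.
#' @param file optional output path; otherwise the rendering is returned.
#' @return A character vector of lines, invisibly when written to `file`.
#' @export
render_tree <- function(hst, style = c("text", "dot"), tags = NULL,
                        file = NULL) {
  stopifnot(inherits(hst, "hst"))
  style <- match.arg(style)
  node_tags <- function(nd) {
    if (is.null(tags) || is.null(nd$indexes) || is.null(hst$row_labels)) {
      return(character(0))
    }
    tg <- tags[hst$row_labels[nd$indexes]]
    sort(unique(tg[!is.na(tg)]))
  }
  if (style == "text") {
    lines <- character(0)
    walk <- function(id, depth) {
      nd <- hst$nodes[[id]]
      span <- if (is.na(nd$lo)) "" else
        paste0(" [", hst$variants$pos[nd$lo], "-", hst$variants$pos[nd$hi],
               ", ", nd$hi - nd$lo + 1L, " markers]")
      tg <- node_tags(nd)
      tagtxt <- if (length(tg)) paste0(" {", paste(tg, collapse = ","), "}") else ""
      lines[length(lines) + 1L] <<- paste0(
        strrep("  ", depth), "n=", nd$n, span, tagtxt)
      for (cid in nd$children) walk(cid, depth + 1L)
    }
    walk(hst$root, 0L)
  } else {
    lines <- c("digraph hst {", "  node [shape=circle];")
    for (nd in hst$nodes) {
      tg <- node_tags(nd)
      extra <- if (length(tg)) {
        paste0(", color=green, xlabel=\"", paste(tg, collapse = ","), "\"")
      } else ""
      lines <- c(lines, paste0("  n", nd$id, " [label=\"", nd$n, "\"",
                               extra, "];"))
    }
    for (nd in hst$nodes) {
      for (cid in nd$children) {
        lines <- c(lines, paste0("  n", nd$id, " -> n", cid, ";"))
      }
    }
    lines <- c(lines, "}")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Plot a haplotype sharing tree
#'
#' Hierarchical layout with nodes labelled by haplotype count; tagged
#' leaves (see [render_tree()]) are drawn in green.
#'
#' @param x an `hst`.
#' @param tags optional named character vector, row label -> tag.
#' @param ... passed to [igraph::plot.igraph()].
#' @method plot hst
#' @export
plot.hst <- function(x, tags = NULL, ...) {
  edges <- unlist(lapply(x$nodes, function(nd) {
    if (!length(nd$children)) return(NULL)
    rbind(nd$id, nd$children)
  }))
  sizes <- vapply(x$nodes, `[[`, integer(1), "n")
  g <- igraph::make_graph(edges = as.character(edges), directed = TRUE)
  ord <- as.integer(igraph::V(g)$name)
  tagged <- vapply(x$nodes, function(nd) {
    !is.null(tags) && !is.null(nd$indexes) && !is.null(x$row_labels) &&
      any(x$row_labels[nd$indexes] %in% names(tags))
  }, logical(1))
  igraph::plot.igraph(
    g, layout = igraph::layout_as_tree(g, root = which(ord == x$root)),
    vertex.label = sizes[ord],
    vertex.color = ifelse(tagged[ord], "palegreen", "lightblue"),
    vertex.size = pmax(8, 4 + 2 * log2(sizes[ord] + 1)),
    edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Plot the comparison matrix
#'
#' One horizontal strip per haplotype over the ancestral haplotype's
#' markers, in the comparison's sort order: mismatches in pink, matches in
#' white for the sample's longer-sharing haplotype and blue for the shorter
#' one.
#'
#' @param comparison an object from [comparison_matrix()].
#' @param file optional PNG path; otherwise draws on the active device.
#' @param width,height device size in pixels when `file` is given.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_segment_matrix <- function(comparison, file = NULL, width = 800,
                                height = 600) {
  stopifnot(inherits(comparison, "hst_comparison"))
  m <- comparison$match
  if (!nrow(m)) stop("empty comparison")
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  # 0 mismatch, 1 match-shorter, 2 match-longer
  longer_sorted <- comparison$longer[comparison$order]
  z <- matrix(0L, nrow(m), ncol(m))
  z[m] <- 1L
  z[m & longer_sorted] <- 2L
  graphics::image(
    x = seq_len(ncol(m)), y = seq_len(nrow(m)),
    z = t(z[rev(seq_len(nrow(m))), , drop = FALSE]),
    col = c("#e377c2", "#1f77b4", "#ffffff"), zlim = c(0, 2),
    xlab = "ancestral haplotype marker", ylab = "haplotype (sorted)",
    useRaster = TRUE)
  graphics::abline(v = match(comparison$start_pos, comparison$positions),
                   lwd = 1)
  invisible(file)
}
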