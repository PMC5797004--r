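# Integrated miRNA-target + gene-gene network: construction, degree
# statistics, top-decile hub detection, Cytoscape-compatible export.

#' Build the integrated interaction network
#'
#' Nodes are the retained genes plus the miRNAs appearing in retained
#' target pairs. Edges are (a) knowledge-base gene-gene edges whose both
#' endpoints are retained and (b) the miRNA-target pairs. The result is an
#' undirected simple graph (self-loops dropped, duplicates merged) with
#' edge provenance kept as an attribute. Knowledge-base edges touching
#' unretained ids are skipped with a warning: a curated knowledge base is
#' by nature a superset of any one study's feature set.
#'
#' @param retainedGenes retained gene DE table (\code{\link{deFilter}}
#'   output; columns \code{feature}, \code{direction}).
#' @param pairs retained target pairs
#'   (\code{\link{tissueSpecificTargetPairs}} output), or an empty
#'   data.frame.
#' @param kbEdges data.frame of gene-gene edges (columns \code{from},
#'   \code{to}), or NULL.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
buildNetwork <- function(retainedGenes, pairs = NULL, kbEdges = NULL) {
  genes <- retainedGenes$feature
  gDir <- setNames(retainedGenes$direction, genes)
  mirs <- character(); mDir <- character()
  edges <- data.frame(from = character(), to = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  if (!is.null(pairs) && nrow(pairs)) {
    mirs <- unique(pairs$mirna)
    mDir <- setNames(pairs$mirna_direction[match(mirs, pairs$mirna)], mirs)
    edges <- rbind(edges, data.frame(from = pairs$mirna, to = pairs$gene,
                                     provenance = "target_pair",
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(kbEdges) && nrow(kbEdges)) {
    known <- kbEdges$from %in% genes & kbEdges$to %in% genes
    if (any(!known))
      warning(sum(!known), " knowledge-base edge(s) reference ",
              "unretained ids; skipped")
    kb <- kbEdges[known, , drop = FALSE]
    if (nrow(kb))
      edges <- rbind(edges, data.frame(from = kb$from, to = kb$to,
                                       provenance = "knowledge_base",
                                       stringsAsFactors = FALSE))
  }
  nodes <- data.frame(
    name = c(genes, mirs),
    nodeClass = c(rep("gene", length(genes)), rep("miRNA", length(mirs))),
    direction = c(unname(gDir), unname(mDir)),
    stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  g <- igraph::simplify(g, edge.attr.comb = list(provenance = "first"))
  new("InteractionNetwork", graph = g)
}

#' Per-node degree statistics
#'
#' Exact incident-edge counts with a dense rank by degree and the hub flag
#' from the top-decile rule. Ordered by degree descending, node id
#' ascending.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param hubFraction fraction for \code{\link{identifyHubs}} (default
#'   0.10).
#' @return data.frame with columns \code{node}, \code{nodeClass},
#'   \code{degree}, \code{rank} (dense, 1 = highest degree),
#'   \code{is_hub}.
#' @export
computeDegree <- function(net, hubFraction = 0.10) {
  stopifnot(is(net, "InteractionNetwork"))
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0)
    return(data.frame(node = character(), nodeClass = character(),
                      degree = integer(), rank = integer(),
                      is_hub = logical(), stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  out <- data.frame(node = names(deg),
                    nodeClass = igraph::V(g)$nodeClass,
                    degree = as.integer(deg), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  out$rank <- match(out$degree, sort(unique(out$degree),
                                     decreasing = TRUE))
  out$is_hub <- out$node %in% identifyHubs(out, hubFraction)
  rownames(out) <- NULL
  out
}

#' Identify hub nodes as the top decile by degree
#'
#' Hubs are the top \code{fraction} of nodes (genes and miRNAs counted
#' jointly) with the highest number of interactions: k =
#' ceiling(fraction x n) nodes by degree, expanded to include every node
#' tied with the k-th degree value, so equal-degree nodes are never split.
#'
#' @param stats degree table (\code{\link{computeDegree}} output, or any
#'   data.frame with \code{node} and \code{degree}).
#' @param fraction in (0, 1]; default 0.10.
#' @return character vector of hub node ids.
#' @export
identifyHubs <- function(stats, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!nrow(stats)) return(character())
  k <- ceiling(fraction * nrow(stats))
  deg <- sort(stats$degree, decreasing = TRUE)
  thr <- deg[k]
  sort(stats$node[stats$degree >= thr])
}

# 5-bin quantile color scale and a linear size scale over degree; the bin
# edges are recorded in the export for reproducibility.
degreeStyle <- function(degree) {
  palette <- c("#ffffcc", "#a1dab4", "#41b6c4", "#2c7fb8", "#253494")
  edges <- unique(quantile(degree, probs = seq(0, 1, 0.2), type = 1))
  bin <- if (length(edges) < 2) rep(1L, length(degree)) else
    findInterval(degree, edges, rightmost.closed = TRUE,
                 all.inside = TRUE)
  maxDeg <- max(degree, 1)
  list(size = 20 + 40 * degree / maxDeg,
       color = palette[bin],
       binEdges = as.numeric(edges))
}

#' Export the network for Cytoscape
#'
#' GraphML (round-trippable, with class/direction/degree/hub/size/color
#' node attributes and the color-scale bin edges as a graph attribute),
#' SIF (one line per edge, provenance as the interaction type), or a plain
#' edge TSV. Output is byte-stable for fixed inputs.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param file output path.
#' @param format \code{"graphml"}, \code{"sif"} or \code{"edge_tsv"}.
#' @param hubFraction passed to \code{\link{computeDegree}} for the node
#'   styling.
#' @return the output path, invisibly.
#' @export
exportGraph <- function(net, file,
                        format = c("graphml", "sif", "edge_tsv"),
                        hubFraction = 0.10) {
  stopifnot(is(net, "InteractionNetwork"))
  format <- match.arg(format)
  g <- networkGraph(net)
  stats <- computeDegree(net, hubFraction)
  idx <- match(igraph::V(g)$name, stats$node)
  style <- degreeStyle(stats$degree[idx])
  igraph::V(g)$degree <- stats$degree[idx]
  igraph::V(g)$is_hub <- stats$is_hub[idx]
  igraph::V(g)$size <- style$size
  igraph::V(g)$color <- style$color
  g <- igraph::set_graph_attr(g, "degree_color_bin_edges",
                              paste(style$binEdges, collapse = ","))
  if (format == "graphml") {
    igraph::write_graph(g, file, format = "graphml")
  } else if (format == "sif") {
    e <- networkEdges(net)
    writeLines(if (nrow(e)) paste(e$from, e$provenance, e$to) else
      character(), file)
  } else {
    e <- networkEdges(net)
    write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Write the per-node attribute table
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param file output TSV path.
#' @param hubFraction hub rule fraction.
#' @return the path, invisibly.
#' @export
writeNodeAttributes <- function(net, file, hubFraction = 0.10) {
  stats <- computeDegree(net, hubFraction)
  nd <- networkNodes(net)
  stats$direction <- nd$direction[match(stats$node, nd$node)]
  write.table(stats, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
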