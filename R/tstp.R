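# Tissue-specific target prediction: the multistep filtration that keeps
# miRNA->gene pairs supported by a prediction database AND inverse
# expression alteration among significantly deregulated features.

#' Tissue-specific target prediction by inverse-expression filtration
#'
#' A miRNA->gene pair is retained iff (i) the miRNA is among the retained
#' (significantly deregulated) miRNAs, (ii) the gene is among the retained
#' genes, (iii) the pair appears in the prediction database with support
#' from at least \code{minSources} distinct sources, and (iv) the two
#' members moved in opposite directions. An optional allow-list restricts
#' the analysis to a tissue-related feature subset.
#'
#' @param deMirnas,deGenes retained DE tables (output of
#'   \code{\link{deFilter}}; columns \code{feature}, \code{direction} with
#'   values \code{"up"}/\code{"down"}).
#' @param db a \linkS4class{TargetPredictionDB}.
#' @param minSources minimum number of distinct database sources
#'   supporting a pair (default 1).
#' @param allowList optional character vector of feature ids (miRNAs
#'   and/or genes); pairs with a member outside the list are dropped.
#' @return data.frame with columns \code{mirna}, \code{mirna_direction},
#'   \code{gene}, \code{gene_direction}, \code{n_sources}, \code{inverse},
#'   ordered by (mirna, gene). Empty DE inputs yield an empty result with
#'   a message.
#' @export
tissueSpecificTargetPairs <- function(deMirnas, deGenes, db,
                                      minSources = 1, allowList = NULL) {
  stopifnot(is(db, "TargetPredictionDB"))
  edges <- dbEdges(db)
  if (!nrow(edges)) stop("empty target-prediction database")
  if (minSources < 1) stop("minSources must be >= 1")
  empty <- data.frame(mirna = character(), mirna_direction = character(),
                      gene = character(), gene_direction = character(),
                      n_sources = integer(), inverse = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(deMirnas) || !nrow(deGenes)) {
    message("tissue-specific target prediction: empty DE input, ",
            "no candidate pairs")
    return(empty)
  }
  mDir <- setNames(deMirnas$direction, deMirnas$feature)
  gDir <- setNames(deGenes$direction, deGenes$feature)
  if (!is.null(allowList)) {
    mDir <- mDir[names(mDir) %in% allowList]
    gDir <- gDir[names(gDir) %in% allowList]
  }
  # distinct source count per candidate pair
  pairs <- unique(edges[c("mirna", "gene")])
  key <- paste(edges$mirna, edges$gene, sep = "\r")
  nSrc <- vapply(split(edges$source, key),
                 function(s) length(unique(s)), integer(1))
  pairs$n_sources <- as.integer(nSrc[paste(pairs$mirna, pairs$gene,
                                           sep = "\r")])
  keep <- pairs$mirna %in% names(mDir) & pairs$gene %in% names(gDir) &
    pairs$n_sources >= minSources
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs)) {
    pairs$mirna_direction <- unname(mDir[pairs$mirna])
    pairs$gene_direction <- unname(gDir[pairs$gene])
    pairs <- pairs[pairs$mirna_direction != pairs$gene_direction &
                     pairs$mirna_direction %in% c("up", "down") &
                     pairs$gene_direction %in% c("up", "down"), ,
                   drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  pairs$inverse <- TRUE
  pairs <- pairs[order(pairs$mirna, pairs$gene),
                 c("mirna", "mirna_direction", "gene", "gene_direction",
                   "n_sources", "inverse")]
  rownames(pairs) <- NULL
  pairs
}

#' Per-pair report with both members' DE statistics
#'
#' Joins a retained pair list with the two DE tables it was derived from.
#'
#' @param pairs output of \code{\link{tissueSpecificTargetPairs}}.
#' @param deMirnas,deGenes the DE tables (columns \code{feature},
#'   \code{log2fc}, \code{p}, \code{adj_p}).
#' @return data.frame, one row per pair, with
#'   \code{mirna_log2fc/p/adj_p} and \code{gene_log2fc/p/adj_p} columns,
#'   ordered by (mirna, gene).
#' @export
pairReport <- function(pairs, deMirnas, deGenes) {
  cols <- c("feature", "log2fc", "p", "adj_p")
  stopifnot(all(cols %in% names(deMirnas)), all(cols %in% names(deGenes)))
  out <- data.frame(mirna = pairs$mirna, gene = pairs$gene,
                    stringsAsFactors = FALSE)
  im <- match(pairs$mirna, deMirnas$feature)
  ig <- match(pairs$gene, deGenes$feature)
  if (anyNA(im) || anyNA(ig)) {
    missing <- c(pairs$mirna[is.na(im)], pairs$gene[is.na(ig)])
    stop("integrity violation: no DE record for pair member(s): ",
         paste(unique(missing), collapse = ", "))
  }
  out$mirna_log2fc <- deMirnas$log2fc[im]
  out$mirna_p <- deMirnas$p[im]
  out$mirna_adj_p <- deMirnas$adj_p[im]
  out$gene_log2fc <- deGenes$log2fc[ig]
  out$gene_p <- deGenes$p[ig]
  out$gene_adj_p <- deGenes$adj_p[ig]
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
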