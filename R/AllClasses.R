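#' @import methods
#' @importFrom stats median pf phyper pt quantile rnbinom rnorm runif sd setNames cor p.adjust complete.cases
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

setOldClass("igraph")

#' ExpressionStudy: a labeled expression matrix for one feature class
#'
#' A \linkS4class{SummarizedExperiment} carrying one assay (\code{"exprs"}),
#' a \code{group} column in \code{colData}, the feature class
#' (\code{"miRNA"} or \code{"mRNA"}) and a flag recording whether the
#' values have been normalized (counts-per-million, log2) or are still raw
#' counts.
#'
#' @slot featureClass character, \code{"miRNA"} or \code{"mRNA"}.
#' @slot normalized logical, \code{TRUE} once values are log2-CPM.
#' @export
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  slots = c(featureClass = "character", normalized = "logical")
)

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (length(object@featureClass) != 1L ||
      !object@featureClass %in% c("miRNA", "mRNA"))
    msg <- c(msg, "featureClass must be one of 'miRNA', 'mRNA'")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "normalized must be TRUE or FALSE")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "feature ids (rownames) must be present and unique")
  if (!isTRUE(object@normalized) && any(assay(object) < 0, na.rm = TRUE))
    msg <- c(msg, "raw counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric matrix, features in rows (unique rownames), samples
#'   in columns.
#' @param groups character vector or factor of group labels, one per sample.
#' @param featureClass \code{"miRNA"} or \code{"mRNA"}.
#' @param normalized logical; \code{FALSE} for raw counts.
#' @param ... further \code{colData} columns (e.g. \code{sizeFactor}).
#' @return An \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rpois(20, 50), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' ExpressionStudy(m, groups = c("a", "a", "a", "b", "b"), "mRNA")
#' @export
ExpressionStudy <- function(exprs, groups, featureClass = c("miRNA", "mRNA"),
                            normalized = FALSE, ...) {
  featureClass <- match.arg(featureClass)
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste0("sample_", seq_len(ncol(exprs)))
  if (length(groups) != ncol(exprs))
    stop("'groups' must have one label per sample (", ncol(exprs),
         " columns, ", length(groups), " labels)")
  cd <- S4Vectors::DataFrame(group = as.character(groups), ...,
                             row.names = colnames(exprs))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("ExpressionStudy", se, featureClass = featureClass,
      normalized = normalized)
}

#' @describeIn ExpressionStudy-class feature class accessor
#' @param object,x an \code{ExpressionStudy}
#' @export
setGeneric("featureClass", function(object) standardGeneric("featureClass"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("featureClass", "ExpressionStudy", function(object)
  object@featureClass)

#' @rdname ExpressionStudy-class
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("isNormalized", "ExpressionStudy", function(object)
  object@normalized)

#' @rdname ExpressionStudy-class
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname ExpressionStudy-class
#' @export
setMethod("sampleGroups", "ExpressionStudy", function(object)
  setNames(SummarizedExperiment::colData(object)$group, colnames(object)))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy (", object@featureClass, "), ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  tab <- table(sampleGroups(object))
  cat("groups:", paste0(names(tab), " (n=", tab, ")", collapse = ", "), "\n")
  cat("values:", if (object@normalized) "log2 CPM" else "raw counts", "\n")
})

#' Simulation configuration for synthetic miRNA/mRNA studies
#'
#' Parameters of the negative-binomial generator. Group log2 means are
#' uniform on \code{baseLog2MeanRange}; a fraction of miRNAs receive a
#' signed resistant-group shift drawn from \code{effectLog2Range} (absolute
#' value; both endpoints must be >= 1 so planted effects clear the 2-fold
#' filter in expectation); each planted miRNA->target pair shifts the
#' gene's resistant-group log2 mean by \code{-coupling} times the miRNA
#' shift (inverse expression).
#'
#' @export
setClass("SimulationConfig", slots = c(
  nMirnas = "numeric", nGenes = "numeric", nSamplesPerGroup = "numeric",
  groups = "character", nTruePairs = "numeric", nDecoyEdges = "numeric",
  coupling = "numeric", baseLog2MeanRange = "numeric",
  nbDispersion = "numeric", deFractionMirna = "numeric",
  deFractionGene = "numeric", effectLog2Range = "numeric",
  librarySizeSdLog = "numeric", seed = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nMirnas = object@nMirnas, nGenes = object@nGenes,
           nSamplesPerGroup = object@nSamplesPerGroup)
  bad <- names(cnt)[cnt < 1 | cnt != round(cnt)]
  if (length(bad))
    msg <- c(msg, paste0(bad, " must be a positive integer", collapse = "; "))
  if (object@nTruePairs < 0 ||
      object@nTruePairs > object@nMirnas * object@nGenes)
    msg <- c(msg, "nTruePairs must be in [0, nMirnas * nGenes]")
  if (object@nDecoyEdges < 0)
    msg <- c(msg, "nDecoyEdges must be >= 0")
  if (object@coupling <= 0)
    msg <- c(msg, "coupling must be > 0")
  if (length(object@groups) < 2 || anyDuplicated(object@groups))
    msg <- c(msg, "groups must be >= 2 distinct labels")
  if (length(object@baseLog2MeanRange) != 2 ||
      diff(object@baseLog2MeanRange) < 0)
    msg <- c(msg, "baseLog2MeanRange must be an increasing interval")
  if (object@nbDispersion <= 0)
    msg <- c(msg, "nbDispersion must be > 0")
  if (object@deFractionMirna < 0 || object@deFractionMirna > 1 ||
      object@deFractionGene < 0 || object@deFractionGene > 1)
    msg <- c(msg, "DE fractions must be in [0, 1]")
  if (length(object@effectLog2Range) != 2 ||
      diff(object@effectLog2Range) < 0 || object@effectLog2Range[1] < 1)
    msg <- c(msg, paste("effectLog2Range must be an increasing interval",
                        "with lower bound >= 1 (clears the 2-fold filter)"))
  if (object@nTruePairs > 0 &&
      object@deFractionMirna * object@nMirnas < 1)
    msg <- c(msg, "nTruePairs > 0 requires at least one shifted miRNA")
  if (length(msg)) msg else TRUE
})

#' @param nMirnas,nGenes numbers of miRNA and mRNA features.
#' @param nSamplesPerGroup samples per group.
#' @param groups ordered group labels; the last is the resistant arm that
#'   carries all planted shifts.
#' @param nTruePairs planted miRNA->target pairs.
#' @param nDecoyEdges prediction-database edges with no planted coupling.
#' @param coupling repression strength, log2 units of gene shift per log2
#'   unit of miRNA shift (> 0).
#' @param baseLog2MeanRange interval for baseline log2 mean expression.
#' @param nbDispersion negative-binomial dispersion (1/size).
#' @param deFractionMirna fraction of miRNAs given a resistant-group shift.
#' @param deFractionGene fraction of genes given a gene-only shift
#'   (independent of any miRNA).
#' @param effectLog2Range interval for |planted shift| (lower bound >= 1).
#' @param librarySizeSdLog sd of log-normal library-size factors.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return A validated \code{SimulationConfig}.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(nMirnas = 300, nGenes = 2000,
                             nSamplesPerGroup = 10,
                             groups = c("control", "sensitive", "resistant"),
                             nTruePairs = 24, nDecoyEdges = 120,
                             coupling = 1,
                             baseLog2MeanRange = c(4, 10),
                             nbDispersion = 0.1,
                             deFractionMirna = 0.05,
                             deFractionGene = 0.05,
                             effectLog2Range = c(1, 3),
                             librarySizeSdLog = 0.1,
                             seed = 1) {
  new("SimulationConfig", nMirnas = nMirnas, nGenes = nGenes,
      nSamplesPerGroup = nSamplesPerGroup, groups = groups,
      nTruePairs = nTruePairs, nDecoyEdges = nDecoyEdges,
      coupling = coupling, baseLog2MeanRange = baseLog2MeanRange,
      nbDispersion = nbDispersion, deFractionMirna = deFractionMirna,
      deFractionGene = deFractionGene, effectLog2Range = effectLog2Range,
      librarySizeSdLog = librarySizeSdLog, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nMirnas, "miRNAs,", object@nGenes,
      "genes,", object@nSamplesPerGroup, "samples/group x",
      length(object@groups), "groups\n")
  cat("planted:", object@nTruePairs, "true pairs,", object@nDecoyEdges,
      "decoy edges, coupling", object@coupling, "\n")
})

#' Ground truth planted by the synthetic-data generator
#'
#' @slot truePairs data.frame with columns \code{mirna}, \code{gene}: the
#'   planted regulatory pairs.
#' @slot plantedMirnaEffects named numeric, signed resistant-group log2
#'   shift per shifted miRNA.
#' @slot plantedGeneEffects named numeric, gene-only shifts.
#' @slot plantedHubs character, node ids planted with inflated edge counts.
#' @export
setClass("TruthSet", slots = c(
  truePairs = "data.frame", plantedMirnaEffects = "numeric",
  plantedGeneEffects = "numeric", plantedHubs = "character"
))

setValidity("TruthSet", function(object) {
  msg <- character()
  tp <- object@truePairs
  if (!all(c("mirna", "gene") %in% names(tp)))
    msg <- c(msg, "truePairs needs columns 'mirna' and 'gene'")
  else if (nrow(tp) &&
           !all(tp$mirna %in% names(object@plantedMirnaEffects)))
    msg <- c(msg, "every true pair's miRNA must carry a planted effect")
  if (length(msg)) msg else TRUE
})

#' @rdname TruthSet-class
#' @param object a \code{TruthSet}
#' @export
setGeneric("truePairs", function(object) standardGeneric("truePairs"))

#' @rdname TruthSet-class
#' @export
setMethod("truePairs", "TruthSet", function(object) object@truePairs)

#' @rdname TruthSet-class
#' @export
setGeneric("plantedEffects", function(object) standardGeneric("plantedEffects"))

#' @rdname TruthSet-class
#' @export
setMethod("plantedEffects", "TruthSet", function(object)
  list(mirna = object@plantedMirnaEffects, gene = object@plantedGeneEffects))

#' @rdname TruthSet-class
#' @export
setGeneric("plantedHubs", function(object) standardGeneric("plantedHubs"))

#' @rdname TruthSet-class
#' @export
setMethod("plantedHubs", "TruthSet", function(object) object@plantedHubs)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@truePairs), "true pairs,",
      length(object@plantedMirnaEffects), "shifted miRNAs,",
      length(object@plantedGeneEffects), "gene-only shifts,",
      length(object@plantedHubs), "planted hub(s)\n")
})

#' miRNA target-prediction database
#'
#' An edge list of predicted miRNA->gene interactions, each tagged with the
#' source database it came from. Duplicate (miRNA, gene, source) triples
#' are not allowed; the same pair may appear under several sources.
#'
#' @slot edges data.frame with columns \code{mirna}, \code{gene},
#'   \code{source}.
#' @export
setClass("TargetPredictionDB", slots = c(edges = "data.frame"))

setValidity("TargetPredictionDB", function(object) {
  e <- object@edges
  if (!all(c("mirna", "gene", "source") %in% names(e)))
    return("edges needs columns 'mirna', 'gene', 'source'")
  if (anyDuplicated(e[c("mirna", "gene", "source")]))
    return("duplicate (mirna, gene, source) triples")
  TRUE
})

#' @rdname TargetPredictionDB-class
#' @param edges data.frame with columns \code{mirna}, \code{gene} and
#'   optionally \code{source} (defaults to \code{"user"}).
#' @export
TargetPredictionDB <- function(edges) {
  edges <- as.data.frame(edges)
  if (!"source" %in% names(edges))
    edges$source <- rep("user", nrow(edges))
  edges <- edges[c("mirna", "gene", "source")]
  edges[] <- lapply(edges, as.character)
  new("TargetPredictionDB", edges = unique(edges))
}

#' @rdname TargetPredictionDB-class
#' @param object a \code{TargetPredictionDB}
#' @export
setGeneric("dbEdges", function(object) standardGeneric("dbEdges"))

#' @rdname TargetPredictionDB-class
#' @export
setMethod("dbEdges", "TargetPredictionDB", function(object) object@edges)

#' @rdname TargetPredictionDB-class
#' @export
setGeneric("dbSources", function(object) standardGeneric("dbSources"))

#' @rdname TargetPredictionDB-class
#' @export
setMethod("dbSources", "TargetPredictionDB", function(object)
  sort(unique(object@edges$source)))

setMethod("show", "TargetPredictionDB", function(object) {
  cat("TargetPredictionDB:", nrow(object@edges), "edges (",
      nrow(unique(object@edges[c("mirna", "gene")])), "distinct pairs ) from",
      length(dbSources(object)), "source(s)\n")
})

#' Differential-expression filter parameters
#'
#' The filtration recipe: keep features with |log2FC| >= log2(fcThreshold)
#' and multiplicity-adjusted p < alpha.
#'
#' @slot fcThreshold fold-change threshold on the natural scale (>= 1;
#'   default 2, i.e. |log2FC| >= 1).
#' @slot alpha significance level (default 0.05).
#' @slot correction \code{"BH"}, \code{"bonferroni"} or \code{"none"}.
#' @export
setClass("DEFilterParams", slots = c(
  fcThreshold = "numeric", alpha = "numeric", correction = "character"
))

setValidity("DEFilterParams", function(object) {
  msg <- character()
  if (object@fcThreshold < 1) msg <- c(msg, "fcThreshold must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!object@correction %in% c("BH", "bonferroni", "none"))
    msg <- c(msg, "correction must be 'BH', 'bonferroni' or 'none'")
  if (length(msg)) msg else TRUE
})

#' @rdname DEFilterParams-class
#' @param fcThreshold,alpha,correction see slots.
#' @export
DEFilterParams <- function(fcThreshold = 2, alpha = 0.05,
                           correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  new("DEFilterParams", fcThreshold = fcThreshold, alpha = alpha,
      correction = correction)
}

setMethod("show", "DEFilterParams", function(object) {
  cat("DEFilterParams: |FC| >=", object@fcThreshold, ", adj p <",
      object@alpha, "(", object@correction, ")\n")
})

#' Integrated miRNA-gene interaction network
#'
#' An undirected simple graph over typed nodes (gene or miRNA). Edges carry
#' a \code{provenance} attribute: \code{"knowledge_base"} for gene-gene
#' edges, \code{"target_pair"} for miRNA-target edges.
#'
#' @slot graph an \code{igraph} undirected simple graph with vertex
#'   attributes \code{nodeClass} and \code{direction}.
#' @export
setClass("InteractionNetwork", slots = c(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g))
    return("graph must be simple (no loops or multi-edges)")
  if (!"nodeClass" %in% igraph::vertex_attr_names(g))
    return("vertices need a 'nodeClass' attribute")
  TRUE
})

#' @rdname InteractionNetwork-class
#' @param object an \code{InteractionNetwork}
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkGraph", "InteractionNetwork", function(object) object@graph)

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork", function(object) {
  g <- object@graph
  data.frame(node = igraph::V(g)$name,
             nodeClass = igraph::V(g)$nodeClass,
             direction = igraph::V(g)$direction,
             stringsAsFactors = FALSE)
})

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkEdges", "InteractionNetwork", function(object) {
  g <- object@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(), to = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  prov <- igraph::edge_attr(g, "provenance")
  if (is.null(prov)) prov <- rep(NA_character_, nrow(el))
  data.frame(from = el[, 1], to = el[, 2],
             provenance = prov, stringsAsFactors = FALSE)
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cls <- table(igraph::V(g)$nodeClass)
  cat("InteractionNetwork:", igraph::vcount(g), "nodes (",
      paste0(names(cls), "=", cls, collapse = ", "), "),",
      igraph::ecount(g), "edges\n")
})
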