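# Gene-set enrichment: one-sided hypergeometric overlap tests with BH or
# Bonferroni correction, activation z-scores for direction-annotated
# sets, and comparison of two enrichment runs.

#' Read gene sets from a GMT file
#'
#' @param file path to a standard GMT file.
#' @return named list of character vectors of member gene ids.
#' @export
readGMT <- function(file) {
  lapply(fgsea::gmtPathways(file), unique)
}

#' Read direction-annotated gene sets
#'
#' Three-column TSV: set id, gene id, expected direction (+1 or -1).
#'
#' @param file path.
#' @return named list; each element a named numeric vector of expected
#'   directions (+1/-1) keyed by gene id.
#' @export
readDirectedSets <- function(file) {
  d <- read.delim(file, header = FALSE,
                  col.names = c("set", "gene", "expected_direction"),
                  stringsAsFactors = FALSE)
  lapply(split(d, d$set), function(s)
    setNames(as.numeric(s$expected_direction), s$gene))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper-tail) hypergeometric p per set: the probability of an
#' overlap at least as large as observed when drawing \code{|query|} genes
#' from the universe. Identical to Fisher's exact one-sided test on the
#' 2x2 overlap table. Sets are intersected with the universe first; sets
#' left empty are skipped with a warning.
#'
#' @param query character vector of gene ids (must be inside
#'   \code{universe}).
#' @param universe character vector, the background (defaults should be
#'   the features actually tested, not the whole genome).
#' @param sets named list of gene-id vectors (\code{\link{readGMT}}).
#' @param correction \code{"BH"}, \code{"bonferroni"} or \code{"none"}.
#' @return data.frame with columns \code{set}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size},
#'   \code{p_value}, \code{adj_p}, sorted by \code{adj_p} then set id.
#' @export
enrich <- function(query, universe, sets,
                   correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query ids outside the universe: ", paste(bad, collapse = ", "))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " set(s) disjoint from the universe; skipped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  N <- length(universe); q <- length(query)
  res <- data.frame(
    set = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, query)),
                     integer(1)),
    set_size = lengths(sets),
    query_size = q, universe_size = N,
    stringsAsFactors = FALSE)
  res$p_value <- phyper(res$overlap - 1, res$set_size, N - res$set_size,
                        q, lower.tail = FALSE)
  res$adj_p <- adjustPvalues(res$p_value, correction)
  res <- res[order(res$adj_p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Activation z-score for a direction-annotated gene set
#'
#' z = (N_consistent - N_inconsistent) / sqrt(N_consistent +
#' N_inconsistent), where a set member is consistent when its observed DE
#' direction equals the expected direction. A simplified, open form of the
#' proprietary upstream-regulator score: positive z indicates activation,
#' negative inhibition. With no scorable members the score is undefined
#' and NA is returned (never 0).
#'
#' @param deGenes DE table (columns \code{feature}, \code{direction} with
#'   \code{"up"}/\code{"down"}).
#' @param expectedDirections named numeric vector (+1/-1) keyed by gene id
#'   (one element of \code{\link{readDirectedSets}}).
#' @return signed numeric z, or NA when no member is scorable.
#' @export
activationZ <- function(deGenes, expectedDirections) {
  obs <- setNames(ifelse(deGenes$direction == "up", 1,
                         ifelse(deGenes$direction == "down", -1, NA)),
                  deGenes$feature)
  common <- intersect(names(expectedDirections),
                      names(obs)[!is.na(obs)])
  if (!length(common)) {
    message("activation z-score: no scorable set members")
    return(NA_real_)
  }
  consistent <- sum(obs[common] == expectedDirections[common])
  inconsistent <- length(common) - consistent
  (consistent - inconsistent) / sqrt(consistent + inconsistent)
}

#' Compare two enrichment runs over the same set collection
#'
#' @param resultsA,resultsB outputs of \code{\link{enrich}} computed on
#'   the same gene-set collection.
#' @param alpha significance level for the Jaccard of significant sets.
#' @return list with \code{table} (per-set side-by-side overlap and
#'   adjusted p), \code{rank_correlation} (Spearman over shared sets) and
#'   \code{jaccard} (of the sets significant in each run at alpha;
#'   defined as 0 when neither run has a significant set).
#' @export
compareEnrichments <- function(resultsA, resultsB, alpha = 0.05) {
  shared <- intersect(resultsA$set, resultsB$set)
  if (!length(shared))
    stop("the two enrichment results share no gene sets")
  tab <- merge(resultsA[c("set", "overlap", "p_value", "adj_p")],
               resultsB[c("set", "overlap", "p_value", "adj_p")],
               by = "set", suffixes = c("_a", "_b"))
  tab <- tab[order(tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  rho <- if (nrow(tab) > 1)
    suppressWarnings(cor(tab$adj_p_a, tab$adj_p_b, method = "spearman"))
  else NA_real_
  sigA <- resultsA$set[resultsA$adj_p < alpha]
  sigB <- resultsB$set[resultsB$adj_p < alpha]
  uni <- union(sigA, sigB)
  jac <- if (length(uni)) length(intersect(sigA, sigB)) / length(uni) else 0
  list(table = tab, rank_correlation = rho, jaccard = jac)
}
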