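# Plain-file interchange formats: expression matrix TSV (features in
# rows, column 1 = feature id), two-column group map, edge-list TSVs,
# truth-set JSON, tidy growth-curve TSV.

#' Write / read an expression study as TSV + group map
#'
#' The matrix TSV has a header row of sample ids and feature ids in the
#' first column (\code{feature}); the group map is a two-column TSV
#' (\code{sample}, \code{group}).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param matrixFile,groupFile output paths.
#' @return paths, invisibly.
#' @export
writeStudy <- function(study, matrixFile, groupFile) {
  m <- assay(study)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrixFile, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(sample = colnames(m), group = unname(sampleGroups(study)),
                   stringsAsFactors = FALSE)
  write.table(gm, groupFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixFile, groupFile))
}

#' @rdname writeStudy
#' @param featureClass,normalized passed to the
#'   \code{\link{ExpressionStudy}} constructor.
#' @export
readStudy <- function(matrixFile, groupFile,
                      featureClass = c("miRNA", "mRNA"),
                      normalized = FALSE) {
  featureClass <- match.arg(featureClass)
  df <- read.delim(matrixFile, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  gm <- read.delim(groupFile, stringsAsFactors = FALSE)
  groups <- gm$group[match(colnames(m), gm$sample)]
  if (anyNA(groups))
    stop("group map lacks sample(s): ",
         paste(colnames(m)[is.na(groups)], collapse = ", "))
  ExpressionStudy(m, groups, featureClass, normalized = normalized)
}

#' Write / read a target-prediction database as three-column TSV
#'
#' @param db a \linkS4class{TargetPredictionDB}.
#' @param file path.
#' @return path / database.
#' @export
writeTargetDB <- function(db, file) {
  write.table(dbEdges(db), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeTargetDB
#' @export
readTargetDB <- function(file) {
  TargetPredictionDB(read.delim(file, stringsAsFactors = FALSE))
}

#' Write a DE table as TSV
#'
#' Columns: feature, log2FC, p, adj_p, direction.
#'
#' @param records DE table from \code{\link{runDE}} / \code{\link{deFilter}}.
#' @param file path.
#' @export
writeDETable <- function(records, file) {
  out <- records
  names(out)[names(out) == "log2fc"] <- "log2FC"
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a truth set as JSON
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param file path.
#' @export
writeTruthSet <- function(truth, file) {
  jsonlite::write_json(list(
    true_pairs = truth@truePairs,
    planted_mirna_effects = as.list(truth@plantedMirnaEffects),
    planted_gene_effects = as.list(truth@plantedGeneEffects),
    planted_hubs = truth@plantedHubs
  ), file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read an allow-list (one feature id per line)
#'
#' @param file path.
#' @return character vector.
#' @export
readAllowList <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x)]
}
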