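# Shared fixtures: a small simulation config and hand-built DE tables.

smallConfig <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nMirnas = 20, nGenes = 80, nSamplesPerGroup = 5, nTruePairs = 6,
         nDecoyEdges = 30, deFractionMirna = 0.25, deFractionGene = 0.1,
         seed = seed),
    list(...))
  do.call(SimulationConfig, args)
}

# a hand-built DE table
deTable <- function(feature, log2fc, adj_p, p = adj_p) {
  data.frame(feature = feature, log2fc = log2fc, p = p, adj_p = adj_p,
             direction = ifelse(abs(log2fc) >= 1,
                                ifelse(log2fc > 0, "up", "down"), "flat"),
             stringsAsFactors = FALSE)
}

# tiny study: 2 groups x n samples, given matrix
toyStudy <- function(m, groups, featureClass = "mRNA", normalized = TRUE) {
  ExpressionStudy(m, groups, featureClass, normalized = normalized)
}

pairKey <- function(d) paste(d$mirna, d$gene)
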