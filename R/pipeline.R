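# End-to-end orchestration: DE -> cross-match -> target filtration ->
# network/hubs (-> enrichment), from one config, with plain-file outputs
# between stages and a JSON run report carrying counts, parameters and
# file checksums.

#' Assemble a pipeline configuration
#'
#' Either synthetic mode (a \linkS4class{SimulationConfig}; inputs are
#' generated) or file mode (paths to the in vivo miRNA/mRNA matrices and
#' group maps, an optional in vitro miRNA study, a target database and an
#' optional knowledge-base edge list).
#'
#' @param synthetic a \linkS4class{SimulationConfig}, or NULL for file
#'   mode.
#' @param files named list of paths (\code{mirnaMatrix}, \code{mirnaGroups},
#'   \code{geneMatrix}, \code{geneGroups}, optional \code{invitroMatrix},
#'   \code{invitroGroups}, \code{targetDB}, optional \code{kbEdges},
#'   optional \code{gmt}).
#' @param comparison character(2): test and reference group labels
#'   (default resistant vs sensitive).
#' @param mirnaParams,geneParams \linkS4class{DEFilterParams} per feature
#'   class.
#' @param minSources,hubFraction,enrichCorrection stage parameters.
#' @param seed integer seed for synthetic generation.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(synthetic = NULL, files = list(),
                           comparison = c("resistant", "sensitive"),
                           mirnaParams = DEFilterParams(),
                           geneParams = DEFilterParams(),
                           minSources = 1, hubFraction = 0.10,
                           enrichCorrection = "bonferroni",
                           seed = 1) {
  if (is.null(synthetic)) {
    need <- c("mirnaMatrix", "mirnaGroups", "geneMatrix", "geneGroups",
              "targetDB")
    miss <- setdiff(need, names(files))
    if (length(miss))
      stop("file mode needs paths: ", paste(miss, collapse = ", "))
    bad <- !vapply(files, file.exists, logical(1))
    if (any(bad))
      stop("input path(s) do not exist: ",
           paste(unlist(files[bad]), collapse = ", "))
  } else stopifnot(is(synthetic, "SimulationConfig"))
  structure(list(synthetic = synthetic, files = files,
                 comparison = comparison, mirnaParams = mirnaParams,
                 geneParams = geneParams, minSources = minSources,
                 hubFraction = hubFraction,
                 enrichCorrection = enrichCorrection, seed = seed),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the \code{\link{pipelineConfig}} arguments;
#' \code{synthetic:} holds \code{SimulationConfig} fields,
#' \code{de_filter:} holds \code{fc_threshold}/\code{alpha}/
#' \code{correction} applied to both feature classes.
#'
#' @param file YAML path.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  y <- yaml::read_yaml(file)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    syn <- SimulationConfig(
      nMirnas = s$n_mirnas %||% 60, nGenes = s$n_genes %||% 400,
      nSamplesPerGroup = s$n_samples_per_group %||% 10,
      nTruePairs = s$n_true_pairs %||% 24,
      nDecoyEdges = s$n_decoy_edges %||% 120,
      coupling = s$coupling %||% 1,
      nbDispersion = s$nb_dispersion %||% 0.1,
      seed = s$seed %||% y$seed %||% 1)
  }
  de <- y$de_filter
  params <- if (is.null(de)) DEFilterParams() else
    DEFilterParams(de$fc_threshold %||% 2, de$alpha %||% 0.05,
                   de$correction %||% "BH")
  pipelineConfig(
    synthetic = syn, files = y$files %||% list(),
    comparison = unlist(y$comparison %||% c("resistant", "sensitive")),
    mirnaParams = params, geneParams = params,
    minSources = y$min_sources %||% 1,
    hubFraction = y$hub_fraction %||% 0.10,
    enrichCorrection = y$enrich_correction %||% "bonferroni",
    seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: (0) synthetic generation or file loading; (1)
#' differential expression for miRNAs and genes (test vs reference
#' comparison); (2) cross-match against the in vitro miRNA study when one
#' is available; (3) tissue-specific target filtration; (4) network
#' construction, degree statistics and hub identification; (5) gene-set
#' enrichment when a GMT is supplied. Every stage writes its output file
#' before the next stage starts; the run is deterministic given the
#' config and seed. A JSON report with per-stage record counts, the
#' parameter echo, versions, wall clock and an output manifest with MD5
#' checksums is written last.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML file).
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly (list; also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  warningsLog <- character()
  noteWarning <- function(w) {
    warningsLog <<- c(warningsLog, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = noteWarning),
             error = function(e)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }
  counts <- list()
  outputs <- character()
  emit <- function(file) { outputs <<- c(outputs, file); file }

  # stage 0: inputs
  invitro <- NULL; kb <- NULL; truth <- NULL; gmt <- NULL
  if (!is.null(config$synthetic)) {
    stage("simulate", {
      cfg <- config$synthetic
      cfg@seed <- config$seed
      sim <- simulateStudy(cfg)
      truth <- sim$truth
      mirStudy <- sim$mirna; genStudy <- sim$gene
      cfg2 <- cfg; cfg2@seed <- cfg@seed + 7919
      invitro <- simulateStudy(cfg2, truth = truth)$mirna
      db <- simulateTargetDB(truth, cfg)
      kb <- simulateKbEdges(rownames(sim$gene), nEdges = cfg@nGenes,
                             seed = cfg@seed + 15485863)
      writeStudy(mirStudy, emit(file.path(outdir, "mirna_counts.tsv")),
                 emit(file.path(outdir, "mirna_groups.tsv")))
      writeStudy(genStudy, emit(file.path(outdir, "gene_counts.tsv")),
                 emit(file.path(outdir, "gene_groups.tsv")))
      writeStudy(invitro, emit(file.path(outdir, "invitro_counts.tsv")),
                 emit(file.path(outdir, "invitro_groups.tsv")))
      writeTargetDB(db, emit(file.path(outdir, "target_db.tsv")))
      write.table(kb, emit(file.path(outdir, "kb_edges.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeTruthSet(truth, emit(file.path(outdir, "truth.json")))
    })
  } else {
    stage("load", {
      f <- config$files
      mirStudy <- readStudy(f$mirnaMatrix, f$mirnaGroups, "miRNA")
      genStudy <- readStudy(f$geneMatrix, f$geneGroups, "mRNA")
      if (!is.null(f$invitroMatrix))
        invitro <- readStudy(f$invitroMatrix, f$invitroGroups, "miRNA")
      db <- readTargetDB(f$targetDB)
      if (!is.null(f$kbEdges))
        kb <- read.delim(f$kbEdges, stringsAsFactors = FALSE)
      if (!is.null(f$gmt)) gmt <- readGMT(f$gmt)
    })
  }

  # stage 1: differential expression
  cmp <- config$comparison
  stage("diffexpr", {
    deMir <- runDE(mirStudy, cmp[1], cmp[2], config$mirnaParams)
    deGen <- runDE(genStudy, cmp[1], cmp[2], config$geneParams)
    writeDETable(deMir, emit(file.path(outdir, "de_mirna.tsv")))
    writeDETable(deGen, emit(file.path(outdir, "de_gene.tsv")))
    keptMir <- deFilter(deMir, config$mirnaParams)
    keptGen <- deFilter(deGen, config$geneParams)
    writeDETable(keptMir, emit(file.path(outdir, "de_mirna_retained.tsv")))
    writeDETable(keptGen, emit(file.path(outdir, "de_gene_retained.tsv")))
    counts$de_mirna_tested <- nrow(deMir)
    counts$de_mirna_retained <- nrow(keptMir)
    counts$de_gene_tested <- nrow(deGen)
    counts$de_gene_retained <- nrow(keptGen)
  })

  # stage 2: cross-match (when an in vitro study is available)
  if (!is.null(invitro)) stage("crossmatch", {
    deInvitro <- runDE(invitro, cmp[1], cmp[2], config$mirnaParams)
    cm <- crossMatch(deInvitro, deMir, config$mirnaParams)
    write.table(cm, emit(file.path(outdir, "crossmatched_mirnas.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$crossmatched_mirnas <- nrow(cm)
  })

  # stage 3: tissue-specific target filtration
  stage("tstp", {
    pairs <- tissueSpecificTargetPairs(keptMir, keptGen, db,
                                        minSources = config$minSources)
    write.table(pairs, emit(file.path(outdir, "target_pairs.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(pairs)) {
      prt <- pairReport(pairs, deMir, deGen)
      write.table(prt, emit(file.path(outdir, "target_pair_report.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    counts$db_edges <- nrow(dbEdges(db))
    counts$target_pairs <- nrow(pairs)
  })

  # stage 4: network + hubs
  stage("network", {
    net <- buildNetwork(keptGen, pairs, kb)
    stats <- computeDegree(net, config$hubFraction)
    exportGraph(net, emit(file.path(outdir, "network.graphml")), "graphml",
                config$hubFraction)
    exportGraph(net, emit(file.path(outdir, "network.sif")), "sif")
    writeNodeAttributes(net, emit(file.path(outdir, "node_attributes.tsv")),
                        config$hubFraction)
    counts$network_nodes <- nrow(stats)
    counts$network_edges <- nrow(networkEdges(net))
    counts$hubs <- sum(stats$is_hub)
  })

  # stage 5: enrichment (needs gene sets)
  if (!is.null(gmt)) stage("enrichment", {
    res <- enrich(keptGen$feature, deGen$feature, gmt,
                  config$enrichCorrection)
    write.table(res, emit(file.path(outdir, "enrichment.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts$gene_sets_tested <- nrow(res)
    counts$gene_sets_significant <- sum(res$adj_p < 0.05)
  })

  report <- list(
    stages = counts,
    parameters = list(
      comparison = cmp,
      mirna_filter = list(fc_threshold = config$mirnaParams@fcThreshold,
                          alpha = config$mirnaParams@alpha,
                          correction = config$mirnaParams@correction),
      gene_filter = list(fc_threshold = config$geneParams@fcThreshold,
                         alpha = config$geneParams@alpha,
                         correction = config$geneParams@correction),
      min_sources = config$minSources,
      hub_fraction = config$hubFraction,
      synthetic = !is.null(config$synthetic),
      seed = config$seed),
    versions = list(
      r = as.character(getRversion()),
      miRTarNet = as.character(packageVersion("miRTarNet"))),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warningsLog,
    manifest = data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      stringsAsFactors = FALSE))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
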