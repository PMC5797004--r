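# Synthetic studies with planted miRNA->target repression. All randomness
# is driven by the seed in the SimulationConfig (or an explicit seed
# argument); the generators restore the caller's RNG state on exit.

withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

mirnaIds <- function(n) sprintf("sim-miR-%03d", seq_len(n))
geneIds  <- function(n) sprintf("simGene%04d", seq_len(n))

#' Simulate paired miRNA and mRNA expression studies with planted coupling
#'
#' Draws negative-binomial counts for two feature classes across the
#' configured groups. A fraction of miRNAs receive a signed log2 shift in
#' the last (resistant) group; each planted miRNA->target pair shifts its
#' gene's resistant-group log2 mean by \code{-coupling} times the miRNA
#' shift, producing the inverse-expression signature the downstream target
#' filtration looks for. A hub miRNA with several targets is always
#' planted (when \code{nTruePairs} allows), mirroring the hub structure of
#' real miRNA-target networks. Library-size factors are drawn log-normal
#' and recorded in \code{colData}.
#'
#' The noiseless group log2 means are stored in
#' \code{metadata(study)$expectedLog2Means} so tests can check the
#' configured means without sampling noise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth optionally a \linkS4class{TruthSet} from a previous call,
#'   to draw a second study (e.g. an in vitro replicate) with the same
#'   planted effects but fresh baselines and noise.
#' @return list with elements \code{mirna}, \code{gene}
#'   (\linkS4class{ExpressionStudy}) and \code{truth}
#'   (\linkS4class{TruthSet}).
#' @examples
#' sim <- simulateStudy(SimulationConfig(nMirnas = 10, nGenes = 40,
#'                                       nTruePairs = 4, nDecoyEdges = 20,
#'                                       seed = 7))
#' sim$mirna
#' truePairs(sim$truth)
#' @export
simulateStudy <- function(config, truth = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, {
    mir <- mirnaIds(config@nMirnas)
    gen <- geneIds(config@nGenes)
    if (is.null(truth)) truth <- plantTruth(config, mir, gen)
    validObject(truth)

    groups <- config@groups
    resistant <- groups[length(groups)]

    baseMir <- runif(config@nMirnas, config@baseLog2MeanRange[1],
                     config@baseLog2MeanRange[2])
    baseGen <- runif(config@nGenes, config@baseLog2MeanRange[1],
                     config@baseLog2MeanRange[2])

    muMir <- matrix(baseMir, config@nMirnas, length(groups),
                    dimnames = list(mir, groups))
    muGen <- matrix(baseGen, config@nGenes, length(groups),
                    dimnames = list(gen, groups))
    eff <- truth@plantedMirnaEffects
    muMir[names(eff), resistant] <- muMir[names(eff), resistant] + eff
    geff <- truth@plantedGeneEffects
    if (length(geff))
      muGen[names(geff), resistant] <- muGen[names(geff), resistant] + geff
    tp <- truth@truePairs
    if (nrow(tp)) {
      shift <- -config@coupling * eff[tp$mirna]
      muGen[tp$gene, resistant] <- muGen[tp$gene, resistant] + shift
    }

    n <- config@nSamplesPerGroup
    sampleGroup <- rep(groups, each = n)
    sampleNames <- paste0(sampleGroup, "_", sprintf("%02d", rep(seq_len(n),
                                                    times = length(groups))))
    sf <- exp(rnorm(length(sampleNames), 0, config@librarySizeSdLog))

    drawCounts <- function(mu) {
      lam <- 2^mu[, sampleGroup, drop = FALSE] *
        rep(sf, each = nrow(mu))
      cnt <- matrix(rnbinom(length(lam), mu = lam,
                            size = 1 / config@nbDispersion),
                    nrow = nrow(mu),
                    dimnames = list(rownames(mu), sampleNames))
      cnt
    }
    mirStudy <- ExpressionStudy(drawCounts(muMir), sampleGroup, "miRNA",
                                sizeFactor = sf)
    genStudy <- ExpressionStudy(drawCounts(muGen), sampleGroup, "mRNA",
                                sizeFactor = sf)
    S4Vectors::metadata(mirStudy)$expectedLog2Means <- muMir
    S4Vectors::metadata(genStudy)$expectedLog2Means <- muGen
    list(mirna = mirStudy, gene = genStudy, truth = truth)
  })
}

# Choose shifted miRNAs, gene-only shifts and true pairs. The first
# shifted miRNA is the planted hub: it takes ~1/3 of the true pairs.
plantTruth <- function(config, mir, gen) {
  nEffM <- round(config@deFractionMirna * config@nMirnas)
  if (config@nTruePairs > 0) nEffM <- max(nEffM, 1L)
  effMir <- sample(mir, nEffM)
  magM <- runif(nEffM, config@effectLog2Range[1], config@effectLog2Range[2])
  sgnM <- sample(c(-1, 1), nEffM, replace = TRUE)
  mirEff <- setNames(sgnM * magM, effMir)

  tp <- data.frame(mirna = character(), gene = character(),
                   stringsAsFactors = FALSE)
  hubs <- character()
  usedGenes <- character()
  if (config@nTruePairs > 0) {
    if (config@nTruePairs > config@nGenes)
      stop("configuration error: nTruePairs (", config@nTruePairs,
           ") exceeds nGenes (", config@nGenes,
           "); each target gene is coupled to one miRNA")
    targets <- sample(gen, config@nTruePairs)
    hub <- effMir[1]
    nHub <- min(config@nTruePairs, max(3L, ceiling(config@nTruePairs / 3)))
    owner <- c(rep(hub, nHub),
               sample(effMir, config@nTruePairs - nHub, replace = TRUE))
    tp <- data.frame(mirna = owner, gene = targets, stringsAsFactors = FALSE)
    hubs <- hub
    usedGenes <- targets
  }
  nEffG <- round(config@deFractionGene * config@nGenes)
  pool <- setdiff(gen, usedGenes)
  nEffG <- min(nEffG, length(pool))
  geneEff <- numeric()
  if (nEffG > 0) {
    effGen <- sample(pool, nEffG)
    geneEff <- setNames(
      sample(c(-1, 1), nEffG, replace = TRUE) *
        runif(nEffG, config@effectLog2Range[1], config@effectLog2Range[2]),
      effGen)
  }
  new("TruthSet", truePairs = tp, plantedMirnaEffects = mirEff,
      plantedGeneEffects = geneEff, plantedHubs = hubs)
}

#' Simulate a target-prediction database around a truth set
#'
#' Returns all planted true pairs plus \code{nDecoyEdges} random non-true
#' pairs, each tagged with a synthetic source label. True pairs may carry
#' one or two sources; decoys carry one.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param config the \linkS4class{SimulationConfig} used to generate it.
#' @return A \linkS4class{TargetPredictionDB}.
#' @export
simulateTargetDB <- function(truth, config) {
  stopifnot(is(truth, "TruthSet"), is(config, "SimulationConfig"))
  mir <- mirnaIds(config@nMirnas)
  gen <- geneIds(config@nGenes)
  tp <- truth@truePairs
  nCells <- length(mir) * length(gen)
  trueIdx <- if (nrow(tp))
    (match(tp$gene, gen) - 1L) * length(mir) + match(tp$mirna, mir)
  else integer()
  nFree <- nCells - length(unique(trueIdx))
  if (config@nDecoyEdges > nFree)
    stop("nDecoyEdges (", config@nDecoyEdges,
         ") exceeds available non-true pairs (", nFree, ")")
  withSeed(config@seed + 104729, {
    sources <- c("synthDB-A", "synthDB-B", "synthDB-C")
    edges <- tp
    edges$source <- sample(sources, nrow(edges), replace = TRUE)
    if (config@nDecoyEdges > 0) {
      decoyIdx <- sample(setdiff(seq_len(nCells), trueIdx),
                         config@nDecoyEdges)
      decoys <- data.frame(
        mirna = mir[(decoyIdx - 1L) %% length(mir) + 1L],
        gene = gen[(decoyIdx - 1L) %/% length(mir) + 1L],
        source = sample(sources, config@nDecoyEdges, replace = TRUE),
        stringsAsFactors = FALSE)
      edges <- rbind(edges, decoys)
    }
    # second-source support for a subset of true pairs
    if (nrow(tp)) {
      extra <- tp[seq_len(ceiling(nrow(tp) / 2)), , drop = FALSE]
      pick <- vapply(seq_len(nrow(extra)), function(i)
        sample(setdiff(sources, edges$source[i]), 1), character(1))
      extra$source <- pick
      edges <- rbind(edges, extra)
    }
    TargetPredictionDB(edges)
  })
}

#' Expected (noiseless) tumor volume of the simulated growth model
#'
#' Vehicle tumors grow exponentially (doubling about weekly); treated
#' tumors shrink slowly until the resistance onset day, then regrow
#' rapidly.
#'
#' @param day numeric vector of days since treatment start.
#' @param arm \code{"vehicle"} or \code{"treated"}.
#' @param onsetDay resistance onset day, or \code{NULL} for no resistance.
#' @param v0 starting volume, mm^3.
#' @return expected volume in mm^3.
#' @export
expectedTumorVolume <- function(day, arm = c("vehicle", "treated"),
                                onsetDay = 28, v0 = 150) {
  arm <- match.arg(arm)
  if (arm == "vehicle") return(v0 * exp(log(2) / 7 * day))
  rS <- -log(2) / 21   # slow shrinkage under treatment
  rR <- log(2) / 5     # rapid regrowth once resistant
  if (is.null(onsetDay)) return(v0 * exp(rS * day))
  ifelse(day <= onsetDay,
         v0 * exp(rS * day),
         v0 * exp(rS * onsetDay) * exp(rR * (day - onsetDay)))
}

#' Simulate caliper growth curves with a resistance changepoint
#'
#' Per-animal series of (day, width, length) measured twice weekly.
#' Volumes follow \code{\link{expectedTumorVolume}}; dimensions are
#' derived assuming a fixed length/width aspect ratio and perturbed with
#' multiplicative log-normal noise. Width never exceeds length
#' (swap-normalized).
#'
#' @param nVehicle,nTreated animals per arm.
#' @param onsetDay resistance onset day for the treated arm (\code{NULL}
#'   for none).
#' @param windowDays length of the observation window in days (> 0).
#' @param noiseSdLog sd of log-normal noise on each caliper dimension
#'   (0 for noiseless curves).
#' @param seed integer seed.
#' @return data.frame with columns \code{animal}, \code{arm}, \code{day},
#'   \code{width_mm}, \code{length_mm}; attribute
#'   \code{resistance_onset_day}.
#' @export
simulateGrowthCurves <- function(nVehicle = 4, nTreated = 7, onsetDay = 28,
                                 windowDays = 70, noiseSdLog = 0.04,
                                 seed = 1) {
  if (windowDays <= 0) stop("empty observation window (windowDays <= 0)")
  if (!is.null(onsetDay) && (onsetDay < 0 || onsetDay > windowDays))
    stop("onsetDay must lie within the observation window")
  days <- sort(unique(c(seq(0, windowDays, by = 7),
                        seq(3, windowDays, by = 7))))  # twice weekly
  aspect <- 1.3
  withSeed(seed, {
    one <- function(animal, arm) {
      v <- expectedTumorVolume(days, arm, onsetDay)
      w <- (2 * v / aspect)^(1 / 3)       # inverts v = w^2 * l / 2, l = a w
      l <- aspect * w
      w <- w * exp(rnorm(length(w), 0, noiseSdLog))
      l <- l * exp(rnorm(length(l), 0, noiseSdLog))
      swap <- w > l
      tmp <- w[swap]; w[swap] <- l[swap]; l[swap] <- tmp
      data.frame(animal = animal, arm = arm, day = days,
                 width_mm = w, length_mm = l, stringsAsFactors = FALSE)
    }
    out <- rbind(
      do.call(rbind, lapply(seq_len(nVehicle), function(i)
        one(sprintf("vehicle_%02d", i), "vehicle"))),
      do.call(rbind, lapply(seq_len(nTreated), function(i)
        one(sprintf("treated_%02d", i), "treated"))))
    attr(out, "resistance_onset_day") <- onsetDay
    out
  })
}

#' Simulate a random gene-gene knowledge-base edge list
#'
#' Uniform random gene pairs, a stand-in for curated gene-gene
#' interactions when exercising the network stage on synthetic data.
#'
#' @param genes character vector of gene ids.
#' @param nEdges number of distinct undirected edges.
#' @param seed integer seed.
#' @return data.frame with columns \code{from}, \code{to}.
#' @export
simulateKbEdges <- function(genes, nEdges, seed = 1) {
  nMax <- length(genes) * (length(genes) - 1) / 2
  if (nEdges > nMax)
    stop("nEdges exceeds the number of distinct gene pairs (", nMax, ")")
  withSeed(seed, {
    g <- igraph::sample_gnm(length(genes), nEdges)
    el <- igraph::as_edgelist(g)
    data.frame(from = genes[el[, 1]], to = genes[el[, 2]],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a random graph with planted hub nodes
#'
#' An Erdos-Renyi background graph plus \code{nHubs} nodes wired to many
#' random partners, for exercising degree-based hub detection.
#'
#' @param nNodes total nodes.
#' @param nHubs planted hubs.
#' @param meanDegree expected background degree.
#' @param hubDegree edges attached to each planted hub.
#' @param seed integer seed.
#' @return list with \code{graph} (igraph) and \code{hubs} (character ids).
#' @export
simulateHubGraph <- function(nNodes = 200, nHubs = 10, meanDegree = 4,
                             hubDegree = 15, seed = 1) {
  stopifnot(nHubs < nNodes, hubDegree < nNodes)
  withSeed(seed, {
    g <- igraph::sample_gnp(nNodes, meanDegree / (nNodes - 1))
    igraph::V(g)$name <- sprintf("node_%03d", seq_len(nNodes))
    hubs <- sample(igraph::V(g)$name, nHubs)
    for (h in hubs) {
      others <- setdiff(igraph::V(g)$name, h)
      g <- igraph::add_edges(g, rbind(h, sample(others, hubDegree)))
    }
    g <- igraph::simplify(g)
    list(graph = g, hubs = hubs)
  })
}
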