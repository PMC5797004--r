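test_that("generation is deterministic and validates its config", {
  cfg <- smallConfig(seed = 11)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(assay(a$mirna), assay(b$mirna))
  expect_identical(assay(a$gene), assay(b$gene))
  expect_identical(truePairs(a$truth), truePairs(b$truth))
  # a different seed changes the draw
  expect_false(identical(assay(a$mirna),
                         assay(simulateStudy(smallConfig(seed = 12))$mirna)))
  expect_error(SimulationConfig(nMirnas = 0), "positive integer")
  expect_error(SimulationConfig(coupling = 0), "coupling")
  expect_error(SimulationConfig(effectLog2Range = c(0.5, 3)),
               "effectLog2Range")
  expect_error(SimulationConfig(nTruePairs = 1e6), "nTruePairs")
})

test_that("planted coupling shifts the configured gene means inversely", {
  cfg <- smallConfig(seed = 5, coupling = 1)
  sim <- simulateStudy(cfg)
  muM <- S4Vectors::metadata(sim$mirna)$expectedLog2Means
  muG <- S4Vectors::metadata(sim$gene)$expectedLog2Means
  eff <- plantedEffects(sim$truth)$mirna
  tp <- truePairs(sim$truth)
  # oracle: configured means without sampling; gene resistant-vs-control
  # shift equals -coupling x miRNA planted shift, exactly
  expect_equal(muG[tp$gene, "resistant"] - muG[tp$gene, "control"],
               setNames(-1 * eff[tp$mirna], tp$gene))
  expect_equal(muM[names(eff), "resistant"] - muM[names(eff), "control"],
               eff)
  # control and sensitive arms carry no planted shift
  expect_equal(muG[, "control"], muG[, "sensitive"])
  # stronger coupling, stronger configured gene shift
  sim2 <- simulateStudy(smallConfig(seed = 5, coupling = 2))
  muG2 <- S4Vectors::metadata(sim2$gene)$expectedLog2Means
  tp2 <- truePairs(sim2$truth)
  expect_equal(muG2[tp2$gene, "resistant"] - muG2[tp2$gene, "control"],
               setNames(-2 * plantedEffects(sim2$truth)$mirna[tp2$mirna],
                        tp2$gene))
})

test_that("no-coupling config plants nothing beyond gene-only effects", {
  cfg <- smallConfig(seed = 2, nTruePairs = 0, nDecoyEdges = 0)
  sim <- simulateStudy(cfg)
  expect_identical(nrow(truePairs(sim$truth)), 0L)
  muG <- S4Vectors::metadata(sim$gene)$expectedLog2Means
  geneOnly <- names(plantedEffects(sim$truth)$gene)
  others <- setdiff(rownames(muG), geneOnly)
  expect_equal(muG[others, "resistant"], muG[others, "control"])
})

test_that("realized gene shifts correlate negatively with planted miRNA shifts", {
  realized <- function(coupling) {
    unlist(lapply(1:10, function(s) {
      sim <- simulateStudy(smallConfig(seed = s, coupling = coupling,
                                       nTruePairs = 12,
                                       nSamplesPerGroup = 8))
      st <- normalizeCpmLog2(sim$gene)
      lfc <- log2FoldChange(st, "resistant", "control")
      tp <- truePairs(sim$truth)
      eff <- plantedEffects(sim$truth)$mirna[tp$mirna]
      cor(eff, lfc[tp$gene])
    }))
  }
  rWeak <- realized(0.25)
  rFull <- realized(1)
  expect_true(mean(rFull) < -0.5)
  # correlation magnitude grows with coupling (better signal-to-noise)
  expect_true(mean(rFull) < mean(rWeak))
  expect_true(mean(rWeak) < 0)
})

test_that("target database contains truth plus exactly the requested decoys", {
  cfg <- smallConfig(seed = 3)
  sim <- simulateStudy(cfg)
  db <- simulateTargetDB(sim$truth, cfg)
  tp <- truePairs(sim$truth)
  pairs <- unique(dbEdges(db)[c("mirna", "gene")])
  expect_true(all(pairKey(tp) %in% pairKey(pairs)))
  # set arithmetic: pairs = true + decoys, no duplicates
  expect_equal(nrow(pairs), nrow(tp) + cfg@nDecoyEdges)
  expect_false(anyDuplicated(dbEdges(db)) > 0)

  cfg0 <- smallConfig(seed = 3, nDecoyEdges = 0)
  db0 <- simulateTargetDB(sim$truth, cfg0)
  expect_setequal(pairKey(unique(dbEdges(db0)[c("mirna", "gene")])),
                  pairKey(tp))
  cfgBig <- smallConfig(seed = 3, nDecoyEdges = 20 * 80)
  expect_error(simulateTargetDB(sim$truth, cfgBig), "exceeds")
})

test_that("decoy-only genes behave as nulls through the DE filter", {
  hits <- vapply(1:10, function(s) {
    cfg <- smallConfig(seed = s, nSamplesPerGroup = 10)
    sim <- simulateStudy(cfg)
    db <- simulateTargetDB(sim$truth, cfg)
    touched <- setdiff(unique(dbEdges(db)$gene),
                       c(truePairs(sim$truth)$gene,
                         names(plantedEffects(sim$truth)$gene)))
    de <- deFilter(runDE(sim$gene, "resistant", "sensitive"))
    sum(touched %in% de$feature) / length(touched)
  }, numeric(1))
  expect_lt(mean(hits), 0.05)
})

test_that("growth curves follow the two-phase mean model", {
  gc <- simulateGrowthCurves(nVehicle = 2, nTreated = 3, onsetDay = 28,
                             seed = 4)
  expect_true(all(gc$width_mm > 0 & gc$length_mm > 0))
  expect_true(all(gc$width_mm <= gc$length_mm))
  byAnimal <- split(gc, gc$animal)
  expect_true(all(vapply(byAnimal, function(a) all(diff(a$day) > 0),
                         logical(1))))
  # noiseless curves: vehicle increasing; treated non-increasing with no
  # onset; with onset 28 the slope changes sign at the changepoint
  d <- sort(unique(gc$day))
  vveh <- expectedTumorVolume(d, "vehicle")
  expect_true(all(diff(vveh) > 0))
  vflat <- expectedTumorVolume(d, "treated", onsetDay = NULL)
  expect_true(all(diff(vflat) <= 0))
  v28 <- expectedTumorVolume(d, "treated", onsetDay = 28)
  sl <- diff(log(v28)) / diff(d)
  expect_true(all(sl[d[-1] <= 28] < 0))
  expect_true(all(sl[d[-length(d)] >= 28] > 0))
  expect_error(simulateGrowthCurves(windowDays = 0), "window")
  expect_error(simulateGrowthCurves(onsetDay = 100, windowDays = 70),
               "onset")
  # determinism
  expect_identical(gc, simulateGrowthCurves(nVehicle = 2, nTreated = 3,
                                            onsetDay = 28, seed = 4))
})

test_that("study TSV round-trips through write/read", {
  sim <- simulateStudy(smallConfig(seed = 9))
  tmp <- withr::local_tempdir()
  mf <- file.path(tmp, "m.tsv"); gf <- file.path(tmp, "g.tsv")
  writeStudy(sim$mirna, mf, gf)
  back <- readStudy(mf, gf, "miRNA")
  expect_equal(assay(back), assay(sim$mirna))
  expect_identical(sampleGroups(back), sampleGroups(sim$mirna))
})
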