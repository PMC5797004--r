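test_that("CPM/log2 normalization matches hand arithmetic", {
  m <- matrix(c(1, 3, 9, 7), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  st <- ExpressionStudy(m, c("a", "b"), "mRNA")
  norm <- normalizeCpmLog2(st)
  # by hand: column totals 4 and 16
  expect_equal(assay(norm),
               matrix(log2(c(1 / 4, 3 / 4, 9 / 16, 7 / 16) * 1e6 + 1), 2, 2,
                      dimnames = dimnames(m)))
  expect_true(isNormalized(norm))
  expect_error(normalizeCpmLog2(norm), "already normalized")

  one <- ExpressionStudy(matrix(1e6, 1, 1, dimnames = list("f", "s")),
                         "a", "miRNA")
  expect_equal(assay(normalizeCpmLog2(one))[1, 1], log2(1e6 + 1))

  dup <- ExpressionStudy(matrix(c(2, 8, 2, 8), 2,
                                dimnames = list(c("f1", "f2"),
                                                c("s1", "s2"))),
                         c("a", "b"), "mRNA")
  nd <- assay(normalizeCpmLog2(dup))
  expect_identical(nd[, 1], nd[, 2])

  z <- ExpressionStudy(matrix(c(1, 2, 0, 0), 2,
                              dimnames = list(c("f1", "f2"),
                                              c("s1", "bad"))),
                       c("a", "b"), "mRNA")
  expect_error(normalizeCpmLog2(z), "bad")
  expect_error(normalizeCpmLog2(st, pseudocount = 0), "pseudocount")
})

test_that("log2 fold change is the test-minus-reference mean difference", {
  m <- rbind(f1 = c(5, 5, 3, 3), f2 = c(2, 4, 2, 4), f3 = c(0, 0, 7, 1))
  colnames(m) <- paste0("s", 1:4)
  st <- toyStudy(m, c("t", "t", "r", "r"))
  lfc <- log2FoldChange(st, "t", "r")
  expect_equal(lfc, c(f1 = 2, f2 = 0, f3 = -4))
  expect_equal(log2FoldChange(st, "r", "t"), -lfc)
  expect_error(log2FoldChange(st, "t", "nope"), "unknown group")
})

test_that("Welch t matches stats::t.test to 1e-10", {
  st <- toyStudy(rbind(f1 = c(1, 2, 3, 4, 5, 6, 7, 8)),
                 rep(c("a", "b"), each = 4))
  res <- welchTest(st, "a", "b")
  or <- t.test(1:4, 5:8)
  expect_equal(res$t, unname(or$statistic), tolerance = 1e-10)
  expect_equal(res$p, or$p.value, tolerance = 1e-10)

  # feature-wise on random matrices vs per-row t.test
  set.seed(42)
  m <- matrix(rnorm(30 * 11, sd = 2), 30,
              dimnames = list(paste0("f", 1:30), NULL))
  g <- rep(c("a", "b"), c(5, 6))
  res <- welchTest(toyStudy(m, g), "a", "b")
  oracle <- t(apply(m, 1, function(x) {
    tt <- t.test(x[g == "a"], x[g == "b"])
    c(tt$statistic, tt$p.value)
  }))
  expect_equal(res$t, unname(oracle[, 1]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle[, 2]), tolerance = 1e-10)
})

test_that("Welch t handles degenerate variance as defined", {
  m <- rbind(same = c(2, 2, 2, 2, 2, 2),
             diff = c(1, 1, 1, 2, 2, 2),
             ok = c(1, 2, 3, 4, 5, 6))
  st <- toyStudy(m, rep(c("a", "b"), each = 3))
  expect_warning(res <- welchTest(st, "a", "b"), "zero variance")
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(is.na(res$p[2]))
  expect_false(is.na(res$p[3]))
  tiny <- toyStudy(rbind(f = c(1, 2, 3)), c("a", "a", "b"))
  expect_error(welchTest(tiny, "a", "b"), ">= 2 samples")
})

test_that("one-way ANOVA matches the classical oracle", {
  set.seed(7)
  m <- matrix(rnorm(20 * 9), 20, dimnames = list(paste0("f", 1:20), NULL))
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anovaOneway(toyStudy(m, g))
  oracle <- t(apply(m, 1, function(x) {
    fit <- summary(aov(x ~ factor(g)))[[1]]
    c(fit$`F value`[1], fit$`Pr(>F)`[1])
  }))
  expect_equal(res$F, unname(oracle[, 1]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle[, 2]), tolerance = 1e-10)

  # degenerate: all values identical -> p = 1 by definition
  flat <- toyStudy(rbind(f = rep(5, 9)), g)
  resF <- anovaOneway(flat)
  expect_equal(resF$p, 1)
  # one shifted group -> F > 0
  sh <- toyStudy(rbind(f = c(0, 0, 0, 0, 0, 0, 5, 5, 5)), g)
  expect_gt(anovaOneway(sh)$F, 0)
  expect_error(anovaOneway(toyStudy(m[, 1:6], g[1:6])), ">= 3 groups")
})

test_that("Welch p approximates the ANOVA p for 2 balanced equal-variance groups", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(16)
    g <- rep(c("a", "b"), each = 8)
    st <- toyStudy(rbind(f = x), g)
    pw <- welchTest(st, "a", "b")$p
    pa <- summary(aov(x ~ factor(g)))[[1]]$`Pr(>F)`[1]
    expect_equal(pw, pa, tolerance = 0.05)
  }
})

test_that("BH and Bonferroni adjustments match manual computation", {
  # manual BH step-up: p (m/i) cummin from the largest
  bhOracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    pmin(1, cummin(p[o] * m / (m:1)))[order(o)]
  }
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))  # manual step-up
  set.seed(3)
  for (i in 1:10) {
    p <- runif(25)^2
    expect_equal(adjustPvalues(p, "BH"), bhOracle(p))
    expect_equal(adjustPvalues(p, "bonferroni"), pmin(1, length(p) * p))
    # monotone when sorted by raw p; never below raw; capped at 1
    adj <- adjustPvalues(p, "BH")
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_equal(adjustPvalues(0.03, "BH"), 0.03)
  expect_equal(adjustPvalues(c(0.03, 0.03), "bonferroni"), c(0.06, 0.06))
  expect_error(adjustPvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the 2-fold + significance filter retains what it should", {
  rec <- deTable(c("a", "b", "c", "d"),
                 log2fc = c(0.9, -1.7, 2.5, -3),
                 adj_p = c(0.001, 0.03615, 0.2, 0.01))
  kept <- deFilter(rec)
  # a: below 2-fold despite tiny p; c: not significant
  expect_setequal(kept$feature, c("b", "d"))
  expect_equal(kept$direction[kept$feature == "b"], "down")
  # idempotent and order-independent
  expect_identical(deFilter(kept), kept)
  shuffled <- rec[c(3, 1, 4, 2), ]
  expect_setequal(deFilter(shuffled)$feature, kept$feature)
  # boundary: |log2fc| exactly 1 is retained (>=), adj_p exactly alpha is not
  edge <- deTable(c("x", "y"), c(1, 2), adj_p = c(0.01, 0.05))
  expect_identical(deFilter(edge)$feature, "x")
})

test_that("planted miRNA effects are recovered with high sensitivity", {
  sens <- vapply(1:10, function(s) {
    sim <- simulateStudy(SimulationConfig(seed = s))
    kept <- deFilter(runDE(sim$mirna, "resistant", "sensitive"))
    eff <- names(plantedEffects(sim$truth)$mirna)
    mean(eff %in% kept$feature)
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})
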