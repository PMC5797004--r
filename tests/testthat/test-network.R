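pairsFrom <- function(mirna, gene) {
  data.frame(mirna = mirna, mirna_direction = "down", gene = gene,
             gene_direction = "up", n_sources = 1L, inverse = TRUE,
             stringsAsFactors = FALSE)
}

test_that("network assembles nodes and edges with dedup and loop dropping", {
  genes <- deTable(c("g1", "g2", "g3"), c(2, 2, 2), adj_p = 0.01)
  pairs <- pairsFrom("m1", "g1")
  net <- buildNetwork(genes, pairs, kbEdges = NULL)
  expect_identical(sort(networkNodes(net)$node), c("g1", "g2", "g3", "m1"))
  expect_identical(nrow(networkEdges(net)), 1L)
  # duplicate kb edge collapses; self-loop dropped; unknown endpoint warns
  kb <- data.frame(from = c("g1", "g1", "g2", "g3", "gX"),
                   to = c("g2", "g2", "g1", "g3", "g1"))
  expect_warning(net2 <- buildNetwork(genes, pairs, kb), "unretained")
  e <- networkEdges(net2)
  expect_identical(nrow(e), 2L)  # m1-g1 and g1-g2
  expect_setequal(e$provenance, c("target_pair", "knowledge_base"))
  # miRNA-gene duplicate of a kb edge keeps a single edge
  expect_true(igraph::is_simple(networkGraph(net2)))
})

test_that("degree statistics are exact and deterministically ordered", {
  # star graph: center degree 5, leaves 1
  genes <- deTable(paste0("g", 1:5), 2, adj_p = 0.01)
  pairs <- pairsFrom(rep("hub", 5), paste0("g", 1:5))
  stats <- computeDegree(buildNetwork(genes, pairs))
  expect_identical(stats$node[1], "hub")
  expect_identical(stats$degree, c(5L, rep(1L, 5)))
  expect_identical(stats$rank, c(1L, rep(2L, 5)))
  expect_identical(stats$node[-1], sort(stats$node[-1]))
  # empty network
  empty <- buildNetwork(deTable(character(), numeric(), numeric()),
                        NULL, NULL)
  expect_identical(nrow(computeDegree(empty)), 0L)
})

test_that("degrees satisfy the handshake identity and match brute force", {
  for (s in 1:5) {
    hg <- simulateHubGraph(nNodes = 60, nHubs = 3, hubDegree = 10, seed = s)
    net <- new("InteractionNetwork",
               graph = igraph::set_vertex_attr(
                 igraph::set_vertex_attr(hg$graph, "nodeClass",
                                         value = "gene"),
                 "direction", value = "up"))
    stats <- computeDegree(net)
    expect_identical(sum(stats$degree),
                     as.integer(2 * igraph::ecount(hg$graph)))
    # brute force: count incident rows in the edge list
    el <- networkEdges(net)
    bf <- table(factor(c(el$from, el$to), levels = stats$node))
    expect_identical(stats$degree, as.integer(bf))
  }
})

test_that("hub rule takes ceiling(fraction x n) nodes and includes ties", {
  # 10 nodes, distinct degrees -> exactly the top one
  st <- data.frame(node = letters[1:10], degree = 10:1)
  expect_identical(identifyHubs(st), "a")
  # 20 nodes, distinct degrees -> top 2
  st20 <- data.frame(node = letters[1:20], degree = 20:1)
  expect_setequal(identifyHubs(st20), c("a", "b"))
  # ranks 1-3 tied -> all three returned even though k = 1
  tied <- data.frame(node = letters[1:10],
                     degree = c(7, 7, 7, 4, 3, 3, 2, 2, 1, 1))
  expect_setequal(identifyHubs(tied), c("a", "b", "c"))
  # oracle: exhaustive threshold scan gives the same set
  thrScan <- function(st, fraction) {
    k <- ceiling(fraction * nrow(st))
    thrs <- sort(unique(st$degree), decreasing = TRUE)
    for (t in thrs) if (sum(st$degree >= t) >= k)
      return(sort(st$node[st$degree >= t]))
  }
  set.seed(9)
  for (i in 1:10) {
    st <- data.frame(node = sprintf("n%02d", 1:30),
                     degree = sample(0:6, 30, replace = TRUE))
    for (f in c(0.05, 0.1, 0.3, 1)) {
      expect_identical(identifyHubs(st, f), thrScan(st, f))
      # monotone: larger fraction is a superset
      expect_true(all(identifyHubs(st, f) %in% identifyHubs(st, 1)))
    }
  }
  expect_identical(identifyHubs(st[0, ]), character())
  expect_error(identifyHubs(st, 0), "fraction")
})

test_that("planted hubs with >= 3x median degree are recovered", {
  hits <- unlist(lapply(1:10, function(s) {
    hg <- simulateHubGraph(nNodes = 200, nHubs = 10, meanDegree = 4,
                           hubDegree = 15, seed = s)
    deg <- igraph::degree(hg$graph)
    stopifnot(min(deg[hg$hubs]) >= 3 * median(deg))
    st <- data.frame(node = names(deg), degree = as.integer(deg))
    hg$hubs %in% identifyHubs(st, 0.10)
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("GraphML export round-trips and styling is monotone in degree", {
  genes <- deTable(paste0("g", 1:6), c(2, -2, 2, 2, -2, 2), adj_p = 0.01)
  pairs <- pairsFrom(c("m1", "m1", "m2"), c("g1", "g3", "g4"))
  kb <- data.frame(from = c("g1", "g2", "g1"), to = c("g2", "g5", "g6"))
  net <- buildNetwork(genes, pairs, kb)
  tmp <- withr::local_tempdir()
  gml <- file.path(tmp, "net.graphml")
  exportGraph(net, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::isomorphic(networkGraph(net), back))
  expect_setequal(igraph::V(back)$name, networkNodes(net)$node)
  v <- igraph::V(back)
  expect_setequal(igraph::vertex_attr_names(back),
                  c("name", "nodeClass", "direction", "degree", "is_hub",
                    "size", "color", "id"))
  # monotone style: higher degree never maps to smaller size
  o <- order(v$degree)
  expect_true(all(diff(v$size[o]) >= 0))
  expect_match(igraph::graph_attr(back, "degree_color_bin_edges"), ",")
  # byte-stable across repeated export
  gml2 <- file.path(tmp, "net2.graphml")
  exportGraph(net, gml2, "graphml")
  expect_identical(readLines(gml), readLines(gml2))

  # SIF: one line per edge, provenance as interaction type
  sif <- file.path(tmp, "net.sif")
  exportGraph(net, sif, "sif")
  lines <- readLines(sif)
  expect_identical(length(lines), nrow(networkEdges(net)))
  expect_true(all(grepl(" (target_pair|knowledge_base) ", lines)))
  two <- buildNetwork(deTable("gA", 2, 0.01), pairsFrom("mB", "gA"))
  sif2 <- file.path(tmp, "two.sif")
  exportGraph(two, sif2, "sif")
  l2 <- readLines(sif2)
  expect_length(l2, 1)  # undirected: endpoint order not fixed
  expect_setequal(strsplit(l2, " ")[[1]], c("mB", "target_pair", "gA"))
  expect_error(exportGraph(net, file.path(tmp, "x"), "dot"))
})
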