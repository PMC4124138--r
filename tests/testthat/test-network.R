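mkGraph <- function(edges, weights = NULL, seeds = character()) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  WeightedGraph(g, weights = weights, seeds = seeds)
}

test_that("node weights are -log10 of the headline adjusted p", {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("gA", "gB", "gC")
  de <- data.frame(gene_id = c("gA", "gB", "gC"),
                   p_headline = c(0.05, 1, 1e-3),
                   consensus = c(TRUE, FALSE, TRUE))
  wg <- assignNodeWeights(g, de)
  w <- nodeWeights(wg)
  expect_equal(unname(w["gA"]), 1.3010, tolerance = 1e-4)
  expect_equal(unname(w["gB"]), 0)
  expect_equal(unname(w["gC"]), 3)
  expect_setequal(seedNodes(wg), c("gA", "gC"))
  de$p_headline[1] <- 0
  expect_error(assignNodeWeights(g, de), "positive")
})

test_that("unmapped nodes get zero weight", {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("gA", "gB", "gX")
  de <- data.frame(gene_id = c("gA", "gB"), p_headline = c(0.01, 0.01),
                   consensus = c(TRUE, TRUE))
  expect_equal(unname(nodeWeights(assignNodeWeights(g, de))["gX"]), 0)
})

test_that("max-weight shortest path picks the heaviest minimum-hop route", {
  ## adjacent nodes: the unique 1-hop path
  wg <- mkGraph(rbind(c("u", "v")), weights = c(u = 2, v = 3))
  res <- maxWeightShortestPath(wg, "u", "v")
  expect_identical(res$path, c("u", "v"))
  expect_equal(res$W, 5)
  ## diamond: two 2-hop routes, the heavier interior node wins
  dia <- mkGraph(rbind(c("u", "a"), c("a", "v"), c("u", "b"), c("b", "v")),
                 weights = c(u = 1, v = 1, a = 2, b = 1))
  res <- maxWeightShortestPath(dia, "u", "v")
  expect_identical(res$path, c("u", "a", "v"))
  expect_equal(res$W, 4)
  ## disconnected pair: explicit no-path result
  two <- mkGraph(rbind(c("u", "a"), c("v", "b")))
  expect_null(maxWeightShortestPath(two, "u", "v"))
  expect_error(maxWeightShortestPath(dia, "u", "u"), "differ")
})

test_that("path extraction matches exhaustive enumeration on random graphs", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, 0.35)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    w <- setNames(round(runif(n, 0, 5), 2), igraph::V(g)$name)
    wg <- WeightedGraph(g, weights = w)
    uv <- sample(igraph::V(g)$name, 2)
    res <- maxWeightShortestPath(wg, uv[1], uv[2])
    oracle <- pathOracle(g, w, uv[1], uv[2])
    if (is.null(oracle)) {
      expect_null(res)
    } else {
      expect_equal(res$W, oracle$W, tolerance = 1e-9)
      expect_identical(res$path, oracle$path)
    }
  }
})

test_that("subnetwork extraction records seeds, linkers and skipped pairs", {
  ## all seeds pairwise adjacent: no linkers
  tri <- mkGraph(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                 seeds = c("a", "b", "c"))
  sn <- extractSubnetwork(tri)
  expect_length(linkerNodes(sn), 0)
  expect_setequal(subnetworkNodes(sn), c("a", "b", "c"))
  ## seeds in different components are skipped, not errors
  split <- mkGraph(rbind(c("a", "x"), c("x", "b"), c("c", "y")),
                   weights = c(a = 1, b = 1, c = 1, x = 5, y = 1),
                   seeds = c("a", "b", "c"))
  sn2 <- extractSubnetwork(split)
  expect_identical(linkerNodes(sn2), "x")
  expect_equal(nrow(sn2@skippedPairs), 2L)
  expect_equal(pathRecords(sn2)[["a|b"]]$W, 7)
  expect_error(extractSubnetwork(mkGraph(rbind(c("a", "b")), seeds = "a")),
               "2 seed")
})

test_that("adding a disconnected component leaves the subnetwork unchanged", {
  set.seed(30)
  g <- igraph::sample_gnp(10, 0.4)
  igraph::V(g)$name <- sprintf("n%02d", 1:10)
  w <- setNames(runif(10, 0, 3), igraph::V(g)$name)
  seeds <- sample(igraph::V(g)$name, 4)
  wg <- WeightedGraph(g, weights = w, seeds = seeds)
  sn1 <- extractSubnetwork(wg)
  extra <- igraph::make_ring(4)
  igraph::V(extra)$name <- paste0("z", 1:4)
  g2 <- igraph::disjoint_union(g, extra)
  wg2 <- WeightedGraph(g2, weights = w, seeds = seeds)
  sn2 <- extractSubnetwork(wg2)
  expect_setequal(subnetworkNodes(sn1), subnetworkNodes(sn2))
  expect_identical(pathRecords(sn1), pathRecords(sn2))
})

test_that("planted module members are recovered in the extracted subnetwork", {
  cfg <- smallConfig(seed = 31L)
  sim <- simulateExpression(cfg)
  pp <- simulatePPI(cfg, sim$truth)
  mod <- plantedModule(pp$truth)
  wg <- WeightedGraph(asIgraph(pp$graph),
                      weights = setNames(rep(2, length(mod)), mod),
                      seeds = mod)
  sn <- extractSubnetwork(wg)
  expect_gte(mean(mod %in% subnetworkNodes(sn)), 0.8)
})

test_that("greedy modularity recovers canonical partitions", {
  tri2 <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"),
          c("d", "e"), c("e", "f"), c("d", "f")), directed = FALSE)
  cm <- detectCommunities(tri2)
  expect_equal(modularityScore(cm), 0.5, tolerance = 1e-12)
  mem <- communityMembership(cm)
  expect_length(unique(mem), 2L)
  expect_length(unique(mem[c("a", "b", "c")]), 1L)
  expect_length(unique(mem[c("d", "e", "f")]), 1L)
  ## brute force over all partitions of the 6 nodes confirms the optimum
  best <- max(vapply(allPartitions(igraph::V(tri2)$name), function(p) {
    assign <- unlist(lapply(seq_along(p), function(i)
      setNames(rep(i, length(p[[i]])), p[[i]])))
    modularityOracle(tri2, assign)
  }, numeric(1)))
  expect_equal(modularityScore(cm), best, tolerance = 1e-12)

  ## complete graph: the single community is the optimum, Q = 0
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  cm5 <- detectCommunities(k5)
  expect_length(unique(communityMembership(cm5)), 1L)
  expect_equal(modularityScore(cm5), 0, tolerance = 1e-12)
  best5 <- max(vapply(allPartitions(letters[1:5]), function(p) {
    assign <- unlist(lapply(seq_along(p), function(i)
      setNames(rep(i, length(p[[i]])), p[[i]])))
    modularityOracle(k5, assign)
  }, numeric(1)))
  expect_equal(modularityScore(cm5), best5, tolerance = 1e-12)
  expect_error(detectCommunities(igraph::make_empty_graph(3, directed = FALSE)),
               "edges")
})

test_that("detected modularity matches the definition and beats one block", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(14, 0.25)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("n%02d", 1:14)
    cm <- detectCommunities(g)
    expect_equal(modularityScore(cm),
                 modularityOracle(g, communityMembership(cm)),
                 tolerance = 1e-12)
    expect_equal(modularityScore(cm),
                 igraph::modularity(g, communityMembership(cm)),
                 tolerance = 1e-12)
    if (igraph::components(g)$no >= 2)
      expect_gte(modularityScore(cm), 0)
  }
})

test_that("community similarity is the Jaccard coefficient", {
  a <- new("CommunityPartition",
           membership = setNames(c(1L, 1L, 2L, 2L), c("A", "B", "C", "D")),
           Q = 0)
  b <- new("CommunityPartition",
           membership = setNames(c(1L, 1L, 2L, 2L), c("B", "C", "E", "F")),
           Q = 0)
  J <- communitySimilarity(a, b)
  expect_equal(J["A1", "B1"], 1 / 3)   # {A,B} vs {B,C}
  expect_equal(J["A2", "B2"], 0)       # disjoint
  self <- communitySimilarity(a, a)
  expect_equal(unname(diag(self)), c(1, 1))  # identical communities
  expect_true(all(J >= 0 & J <= 1))
  expect_equal(unname(communitySimilarity(b, a)), unname(t(J)))
})

test_that("secretory subnetworks keep annotated nodes plus neighbors", {
  star <- igraph::graph_from_edgelist(
    rbind(c("hub", "n1"), c("hub", "n2"), c("hub", "n3"), c("n3", "n4")),
    directed = FALSE)
  sn <- new("Subnetwork", graph = star, seeds = c("hub", "n4"),
            linkers = c("n1", "n2", "n3"))
  gs <- geneSetList(list("GO:0042428" = c("hub"),
                         "GO:0030141" = c("n9")),
                    namespace = "secretory")
  out <- secretorySubnetwork(sn, gs, c("GO:0042428", "GO:0030141"))
  expect_setequal(subnetworkNodes(out), c("hub", "n1", "n2", "n3"))
  info <- out@nodeInfo
  expect_identical(info$status[info$node == "hub"], "annotated")
  expect_identical(info$status[info$node == "n1"], "neighbor")
  ## two annotated nodes sharing a neighbor: neighbor appears once
  gs2 <- geneSetList(list("GO:0007218" = c("n1", "n2")),
                     namespace = "secretory")
  out2 <- secretorySubnetwork(sn, gs2, "GO:0007218")
  expect_identical(sum(out2@nodeInfo$node == "hub"), 1L)
  expect_identical(out2@nodeInfo$status[out2@nodeInfo$node == "hub"],
                   "neighbor")
  ## no annotated nodes -> empty; unknown term warned
  expect_warning(out3 <- secretorySubnetwork(sn, gs2,
                                             c("GO:0007218", "GO:9999999")),
                 "skipped")
  empty <- suppressWarnings(secretorySubnetwork(sn, gs, "GO:0030141"))
  expect_length(subnetworkNodes(empty), 0)
})
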