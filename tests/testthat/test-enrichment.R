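test_that("hypergeometric enrichment applies the exact tail and size filter", {
  universe <- sprintf("g%02d", 1:10)
  gs <- geneSetList(list(big = universe[1:5], small = universe[1:9]),
                    namespace = c("BP", "BP"))
  ## term of size 9 with minSize = 10 is excluded
  res <- hypergeometricEnrichment(universe[1:4], universe, gs, minSize = 10L)
  expect_false("small" %in% res$term_id)
  expect_false("big" %in% res$term_id)
  ## N = 10, K = 5, n = 4, k = 4: p = C(5,4) / C(10,4) = 5/210
  res2 <- hypergeometricEnrichment(universe[1:4], universe, gs, minSize = 2L)
  expect_equal(res2$p[res2$term_id == "big"], 5 / 210, tolerance = 1e-12)
  ## de = universe: k = K for every term and p = 1
  resAll <- hypergeometricEnrichment(universe, universe, gs, minSize = 2L)
  expect_true(all(resAll$k == resAll$K))
  expect_true(all(resAll$p == 1))
  expect_error(hypergeometricEnrichment(character(), universe, gs), "empty")
})

test_that("hypergeometric p equals the exhaustive-draw oracle", {
  universe <- sprintf("g%02d", 1:9)
  term <- universe[c(1, 3, 5, 7)]
  gs <- geneSetList(list(t = term))
  for (n in c(2, 4, 6)) {
    de <- universe[1:n]
    res <- hypergeometricEnrichment(de, universe, gs, minSize = 2L)
    k <- length(intersect(term, de))
    ## enumerate all C(9, n) possible DE draws
    draws <- combn(9, n)
    hits <- apply(draws, 2, function(ix)
      length(intersect(universe[ix], term)) >= k)
    expect_equal(res$p, mean(hits), tolerance = 1e-12)
  }
})

test_that("adding a non-DE gene to a term never decreases its p", {
  universe <- sprintf("g%02d", 1:12)
  de <- universe[1:4]
  for (K in 4:8) {
    gsA <- geneSetList(list(t = c(de[1:3], universe[5:(K + 1)])))
    gsB <- geneSetList(list(t = c(de[1:3], universe[5:(K + 2)])))
    pA <- hypergeometricEnrichment(de, universe, gsA, minSize = 2L)$p
    pB <- hypergeometricEnrichment(de, universe, gsB, minSize = 2L)$p
    expect_gte(pB, pA - 1e-12)
  }
})

test_that("BH adjustment is applied within each namespace", {
  universe <- sprintf("g%02d", 1:20)
  gs <- geneSetList(list(a1 = universe[1:5], a2 = universe[6:10],
                         b1 = universe[1:5]),
                    namespace = c("BP", "BP", "CC"))
  res <- hypergeometricEnrichment(universe[1:5], universe, gs, minSize = 2L)
  bp <- res[res$namespace == "BP", ]
  cc <- res[res$namespace == "CC", ]
  expect_equal(bp$p_adj, bhOracle(bp$p))
  expect_equal(cc$p_adj, cc$p)  # single term in its namespace
})

test_that("exact set-activation posteriors match a direct enumeration", {
  set.seed(20)
  universe <- sprintf("g%02d", 1:30)
  sets <- list(S1 = universe[1:8], S2 = universe[7:14], S3 = universe[15:20],
               S4 = universe[c(2, 16, 21:24)])
  gs <- geneSetList(sets)
  de <- c(universe[1:7], universe[25])
  res <- mgsa(de, universe, gs, alpha = 0.1, beta = 0.25, prior = 0.1)
  expect_identical(res@method, "exact")
  oracle <- mgsaOracle(sets, universe, de, alpha = 0.1, beta = 0.25,
                       prior = 0.1)
  expect_equal(setPosterior(res), oracle, tolerance = 1e-9)
})

test_that("set-activation model respects symmetry and degenerate inputs", {
  universe <- sprintf("g%02d", 1:20)
  twin <- list(A = universe[1:6], B = universe[1:6], C = universe[10:15])
  res <- mgsa(universe[1:6], universe, geneSetList(twin))
  post <- setPosterior(res)
  expect_equal(unname(post["A"]), unname(post["B"]), tolerance = 1e-12)
  empty <- mgsa(universe[1:3], universe,
                geneSetList(stats::setNames(list(), character())))
  expect_length(setPosterior(empty), 0)
  expect_error(mgsa(universe[1:3], universe, geneSetList(twin), alpha = 0.7),
               "0, 0.5")
})

test_that("MCMC posteriors agree with exact enumeration on an ambiguous toy", {
  set.seed(21)
  universe <- sprintf("g%02d", 1:40)
  sets <- lapply(1:6, function(i) sample(universe, 10))
  names(sets) <- paste0("S", 1:6)
  gs <- geneSetList(sets)
  de <- unique(c(sets$S3[1:7], sample(universe, 5)))
  exact <- mgsa(de, universe, gs, exactLimit = 20L)
  mcmc <- mgsa(de, universe, gs, exactLimit = 2L, nSweeps = 1e5, seed = 9L)
  expect_identical(mcmc@method, "mcmc")
  expect_lt(max(abs(setPosterior(exact) - setPosterior(mcmc))), 0.05)
})

test_that("planted enriched sets get higher posteriors than background", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- smallConfig(seed = s, nGeneSets = 6L, nEnrichedSets = 2L)
    sim <- simulateExpression(cfg)
    gs <- simulateGeneSets(cfg, sim$truth)
    res <- mgsa(deGenes(sim$truth),
                sprintf("G%05d", seq_len(cfg@nGenes)), gs$genesets,
                exactLimit = 14L)
    post <- setPosterior(res)
    planted <- enrichedSets(gs$truth)
    bg <- setdiff(names(post), planted)
    wins <- wins + (mean(post[planted]) > mean(post[bg]))
  }
  expect_gte(wins / 10, 0.9)
})

test_that("enrichment overlap reports min-based and Jaccard fractions", {
  mk <- function(ids, p) data.frame(term_id = ids, p_adj = p)
  a <- mk(c("t1", "t2", "t3", "t4"), rep(0.01, 4))
  b <- mk(c("t3", "t4", "t5"), rep(0.01, 3))
  ov <- enrichmentOverlap(a, b)
  expect_equal(ov$overlap, 2 / 3)
  expect_equal(ov$jaccard, 2 / 5)
  expect_equal(enrichmentOverlap(a, a)$overlap, 1)
  expect_equal(enrichmentOverlap(a, mk("t9", 0.01))$overlap, 0)
  expect_equal(enrichmentOverlap(mk("t1", 0.9), mk("t1", 0.9))$overlap, 0)
})
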