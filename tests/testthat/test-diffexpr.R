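test_that("fold changes and their signed form follow the conventions", {
  gm <- toyGeneMatrix(tumor = cbind(c(7, 5), c(7, 5), c(7, 5)),
                      normal = cbind(c(5, 5), c(5, 5), c(5, 5)))
  lfc <- log2FoldChange(gm)
  expect_equal(unname(lfc), c(2, 0))
  expect_equal(signedFoldChange(c(2, -1, 0)), c(4, -2, 1))
})

test_that("ordinary t matches the pooled-variance closed form", {
  gm <- toyGeneMatrix(tumor = matrix(c(3, 4, 5), 1), normal = matrix(0:2, 1))
  res <- ordinaryT(gm)
  ## diff = 3, pooled s^2 = 1, t = 3 / sqrt(2/3), df = 4
  expect_equal(res$t, 3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$t, 3.674, tolerance = 1e-3)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), df = 4))
  ## identical groups: t = 0, p = 1
  same <- toyGeneMatrix(tumor = matrix(c(1, 2, 3), 1),
                        normal = matrix(c(1, 2, 3), 1))
  expect_equal(ordinaryT(same)$t, 0)
  expect_equal(ordinaryT(same)$p, 1)
})

test_that("all five statistics are antisymmetric under group-label swap", {
  set.seed(10)
  x <- matrix(rnorm(40 * 8, 7, 1), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:8)))
  g1 <- rep(c("tumor", "normal"), each = 4)
  g2 <- rep(c("normal", "tumor"), each = 4)
  gma <- GeneMatrix(x, g1); gmb <- GeneMatrix(x, g2)
  expect_equal(log2FoldChange(gma), -log2FoldChange(gmb))
  expect_equal(ordinaryT(gma)$t, -ordinaryT(gmb)$t)
  expect_equal(shrinkageT(gma)$t, -shrinkageT(gmb)$t)
  expect_equal(moderatedT(gma)$t, -moderatedT(gmb)$t)
  sa <- samStatistic(gma, nPermutations = 50L, seed = 1L)
  sb <- samStatistic(gmb, nPermutations = 50L, seed = 1L)
  expect_equal(sa$d, -sb$d)
})

test_that("shrinkage t matches a straight-line recomputation on a toy", {
  set.seed(11)
  tumor <- matrix(rnorm(5 * 4, 8, c(0.2, 0.5, 1, 2, 4)), 5, 4)
  normal <- matrix(rnorm(5 * 3, 7, c(0.2, 0.5, 1, 2, 4)), 5, 3)
  gm <- toyGeneMatrix(tumor, normal)
  res <- shrinkageT(gm)

  ## independent recomputation of the formulas
  n1 <- 4; n2 <- 3
  v <- vv <- r <- numeric(5)
  for (gidx in 1:5) {
    xt <- tumor[gidx, ]; xn <- normal[gidx, ]
    r[gidx] <- mean(xt) - mean(xn)
    v[gidx] <- (sum((xt - mean(xt))^2) + sum((xn - mean(xn))^2)) / (n1 + n2 - 2)
    vo <- function(z) {
      w <- (z - mean(z))^2
      length(z) / (length(z) - 1)^3 * sum((w - mean(w))^2)
    }
    vv[gidx] <- ((n1 - 1)^2 * vo(xt) + (n2 - 1)^2 * vo(xn)) / (n1 + n2 - 2)^2
  }
  vmed <- median(v)
  lambda <- min(1, sum(vv) / sum((v - vmed)^2))
  vstar <- lambda * vmed + (1 - lambda) * v
  tstar <- r / sqrt(vstar * (1 / n1 + 1 / n2))
  expect_equal(attr(res, "lambda"), lambda, tolerance = 1e-12)
  expect_equal(res$t, tstar, tolerance = 1e-12)
})

test_that("equal gene variances make shrinkage irrelevant", {
  ## identical spread pattern in every gene: v_g all equal, so v* = v and
  ## t* equals the ordinary t whatever lambda is
  base <- rbind(c(1, 2, 3, 1, 2, 3), c(2, 3, 4, 1, 2, 3),
                c(5, 6, 7, 2, 3, 4))
  gm <- GeneMatrix(matrix(base, 3, 6,
                          dimnames = list(paste0("g", 1:3), paste0("s", 1:6))),
                   rep(c("tumor", "normal"), each = 3))
  expect_equal(shrinkageT(gm)$t, ordinaryT(gm)$t, tolerance = 1e-12)
})

test_that("moderated t limits behave as the theory dictates", {
  set.seed(12)
  x <- matrix(rnorm(20 * 10, 7, rep(c(0.3, 1, 3), length.out = 20)), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
  gm <- GeneMatrix(x, rep(c("tumor", "normal"), each = 5))
  ## d0 = 0 forced reproduces the ordinary t
  expect_equal(moderatedT(gm, d0 = 0)$t, ordinaryT(gm)$t, tolerance = 1e-12)
  ## estimated: posterior variance is a strict convex combination
  res <- moderatedT(gm)
  d0 <- attr(res, "d0"); s02 <- attr(res, "s02")
  expect_true(is.finite(d0) && d0 > 0)
  s <- ordinaryT(gm)  # recover s2 via t
  s2 <- (log2FoldChange(gm) / s$t)^2 / (1 / 5 + 1 / 5)
  s2post <- (d0 * s02 + 8 * s2) / (d0 + 8)
  lo <- pmin(s2, s02); hi <- pmax(s2, s02)
  expect_true(all(s2post > lo & s2post < hi))
  expect_equal(res$t, unname(log2FoldChange(gm) /
                 sqrt(s2post * (1 / 5 + 1 / 5))), tolerance = 1e-9)

  ## identical sample variances in every gene force the d0 = Inf limit
  flat <- matrix(rep(c(1, 2, 3, 4, 1, 2, 3, 4), 5), 5, 8, byrow = TRUE) +
    matrix(c(0, 1, 2, 3, 4), 5, 8)
  dimnames(flat) <- list(paste0("g", 1:5), paste0("s", 1:8))
  gmf <- GeneMatrix(flat, rep(c("tumor", "normal"), each = 4))
  resf <- moderatedT(gmf)
  expect_identical(attr(resf, "d0"), Inf)
})

test_that("SAM d uses the fudged denominator and decreases with s0", {
  set.seed(13)
  x <- matrix(rnorm(30 * 6, 7, 1), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  gm <- GeneMatrix(x, rep(c("tumor", "normal"), each = 3))
  res <- samStatistic(gm, nPermutations = 50L, seed = 2L)
  s0 <- attr(res, "s0")
  expect_gte(s0, 0)
  lfc <- log2FoldChange(gm)
  se <- lfc / ordinaryT(gm)$t     # pooled standard error
  expect_equal(res$d, unname(lfc / (se + s0)), tolerance = 1e-9)
  ## with s0 = 0 the statistic is exactly the ordinary t; d is monotone
  ## decreasing in s0 for positive differences
  expect_equal(unname(lfc / (se + 0)), ordinaryT(gm)$t, tolerance = 1e-9)
  pos <- which(lfc > 0)
  expect_true(all(lfc[pos] / (se[pos] + s0 + 1) < lfc[pos] / (se[pos] + s0)))
})

test_that("2v2 permutation p-values equal exhaustive enumeration", {
  x <- matrix(c(5.1, 4.8, 1.2, 0.9,
                3.0, 3.1, 3.2, 2.9), 2, 4, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  gm <- GeneMatrix(x, c("tumor", "tumor", "normal", "normal"))
  res <- samStatistic(gm, nPermutations = 1000L, seed = 3L)
  expect_true(attr(res, "exact"))  # C(4,2) = 6 < 20 distinct splits

  ## brute force over the 6 splits
  s0 <- attr(res, "s0")
  dOf <- function(ix) {
    stat <- numeric(2)
    for (gidx in 1:2) {
      xt <- x[gidx, ix]; xn <- x[gidx, -ix]
      sp <- sqrt((sum((xt - mean(xt))^2) + sum((xn - mean(xn))^2)) / 2)
      stat[gidx] <- (mean(xt) - mean(xn)) / (sp * sqrt(1 / 2 + 1 / 2) + s0)
    }
    stat
  }
  splits <- combn(4, 2)
  dAll <- apply(splits, 2, dOf)
  dObs <- dOf(1:2)
  pOracle <- rowMeans(abs(dAll) >= abs(dObs) - 1e-12)
  expect_equal(res$p, pOracle)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjustBH(0.02), 0.02)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(14)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))^2
    expect_equal(adjustBH(p), bhOracle(p), tolerance = 1e-12)
    expect_true(all(adjustBH(p) >= p))
  }
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
})

test_that("consensus requires agreement of the required method count", {
  genes <- c("g1", "g2", "g3")
  lfc <- setNames(c(2.5, 2.5, 0.2), genes)  # g3 fails the FC ranker
  mk <- function(p) data.frame(t = c(5, 5, 5), p = p, row.names = genes)
  strong <- c(1e-6, 1e-6, 1e-6)
  weakG2 <- c(1e-6, 0.9, 1e-6)
  allSig <- consensusCalls(lfc, mk(strong), mk(strong), mk(strong),
                           setNames(data.frame(d = c(5, 5, 5), p = strong,
                                               row.names = genes),
                                    c("d", "p")))
  expect_true(allSig["g1", "consensus"])
  expect_false(allSig["g3", "consensus"])      # 4 of 5 at mRequired = 5
  expect_identical(allSig["g3", "n_methods_significant"], 4L)
  fourOf5 <- consensusCalls(lfc, mk(weakG2), mk(strong), mk(strong),
                            setNames(data.frame(d = c(5, 5, 5), p = strong,
                                                row.names = genes),
                                     c("d", "p")))
  expect_false(fourOf5["g2", "consensus"])
  relaxed <- consensusCalls(lfc, mk(weakG2), mk(strong), mk(strong),
                            setNames(data.frame(d = c(5, 5, 5), p = strong,
                                                row.names = genes),
                                     c("d", "p")),
                            config = deConfig(mRequired = 4L))
  expect_true(relaxed["g2", "consensus"])
  ## headline p is the max over the four statistics' adjusted p
  expect_equal(fourOf5["g2", "p_headline"],
               max(adjustBH(weakG2)[2], adjustBH(strong)[2]))
})

test_that("full consensus is contained in every per-method call set", {
  sim <- simulateExpression(smallConfig(seed = 15L))
  res <- suppressWarnings(analyzeStudy(sim$expression, sim$mapping,
                                       deConfig(nPermutations = 1000L)))
  de <- res$de
  cons <- de[de$consensus, ]
  expect_true(all(abs(cons$log2fc) >= 1))
  for (col in c("padj_t_ordinary", "padj_t_shrink", "padj_t_moderated",
                "padj_d_sam"))
    expect_true(all(cons[[col]] <= 0.05))
})
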