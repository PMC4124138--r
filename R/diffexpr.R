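## Consensus differential expression: fold-change ranking plus four
## regularized/classical t-like statistics (ordinary t, shrinkage t,
## moderated t, SAM d) with BH adjustment, combined into a consensus call.

#' Differential expression configuration
#'
#' @param alpha adjusted-p significance threshold per method (default 0.05).
#' @param fcThreshold |log2 fold change| cutoff for the fold-change ranker
#'   (default 1, i.e. two-fold).
#' @param mRequired number of the five methods that must agree for a
#'   consensus call (default 5, full intersection).
#' @param nPermutations label permutations for the SAM p-value.
#' @param seed RNG seed for the permutations.
#' @return A list of class `DEConfig`.
#' @export
deConfig <- function(alpha = 0.05, fcThreshold = 1, mRequired = 5L,
                     nPermutations = 1000L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, mRequired >= 1L, mRequired <= 5L)
  structure(list(alpha = alpha, fcThreshold = fcThreshold,
                 mRequired = as.integer(mRequired),
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)),
            class = "DEConfig")
}

## shared two-group summaries on a genes x samples log2 matrix
.groupSummaries <- function(x, groups) {
  groups <- as.character(groups)
  it <- groups == "tumor"; inn <- groups == "normal"
  n1 <- sum(it); n2 <- sum(inn)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  m1 <- rowMeans(x[, it, drop = FALSE])
  m2 <- rowMeans(x[, inn, drop = FALSE])
  ss1 <- rowSums((x[, it, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, inn, drop = FALSE] - m2)^2)
  list(diff = m1 - m2, ss1 = ss1, ss2 = ss2, n1 = n1, n2 = n2,
       pooledVar = (ss1 + ss2) / (n1 + n2 - 2),
       scale = sqrt(1 / n1 + 1 / n2), df = n1 + n2 - 2)
}

.asMatrixGroups <- function(g, groups = NULL) {
  if (is(g, "GeneMatrix")) list(x = log2Values(g), groups = sampleGroups(g))
  else list(x = as.matrix(g), groups = groups)
}

#' Log2 fold change (tumor minus normal)
#'
#' @param g a [GeneMatrix-class] (or matrix with `groups` supplied).
#' @param groups optional group labels when `g` is a plain matrix.
#' @return Named numeric of per-gene log2 fold changes.
#' @export
log2FoldChange <- function(g, groups = NULL) {
  mg <- .asMatrixGroups(g, groups)
  .groupSummaries(mg$x, mg$groups)$diff
}

#' Signed linear fold change
#'
#' Converts a log2 fold change `x` to `+2^x` for `x >= 0` and `-2^(-x)`
#' otherwise (so +2 -> +4, -1 -> -2, 0 -> +1), the signed presentation
#' conventional for microarray tables.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return Signed linear fold changes.
#' @export
signedFoldChange <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Ordinary two-sample t-statistic
#'
#' Pooled-variance t with `n1 + n2 - 2` degrees of freedom and two-sided
#' p-values. Genes with zero within-group variance get `t = +/-Inf` and
#' `p = 0`, with a warning.
#'
#' @inheritParams log2FoldChange
#' @return data.frame with columns `t` and `p`, rownames = genes.
#' @export
ordinaryT <- function(g, groups = NULL) {
  mg <- .asMatrixGroups(g, groups)
  s <- .groupSummaries(mg$x, mg$groups)
  se <- sqrt(s$pooledVar) * s$scale
  t <- s$diff / se
  if (any(se == 0)) {
    warning("zero within-group variance: t set to +/-Inf, p to 0")
    t[se == 0] <- sign(s$diff[se == 0]) * Inf
    t[se == 0 & s$diff == 0] <- 0
  }
  p <- 2 * stats::pt(-abs(t), df = s$df)
  p[is.infinite(t)] <- 0
  data.frame(t = t, p = p, row.names = rownames(mg$x))
}

#' Shrinkage t-statistic
#'
#' Per-gene pooled variances are shrunk toward their median:
#' `v* = lambda * v_med + (1 - lambda) * v` with the adaptive weight
#' `lambda = min(1, sum(Var_hat(v_g)) / sum((v_g - v_med)^2))`, where
#' `Var_hat(v_g)` is the standard unbiased estimate of the sampling variance
#' of each group's variance (from the squared centered observations),
#' pooled across groups. The statistic is `diff / sqrt(v* (1/n1 + 1/n2))`;
#' p-values use the t distribution with `n1 + n2 - 2` df (an approximation:
#' the exact null of a shrunken denominator is not t).
#'
#' @inheritParams log2FoldChange
#' @return data.frame with columns `t`, `p` and attribute `lambda`.
#' @export
shrinkageT <- function(g, groups = NULL) {
  mg <- .asMatrixGroups(g, groups)
  x <- mg$x
  if (nrow(x) < 3L) {
    warning("fewer than 3 genes: shrinkage target ill-defined, ",
            "falling back to the ordinary t")
    out <- ordinaryT(x, mg$groups)
    attr(out, "lambda") <- 0
    return(out)
  }
  s <- .groupSummaries(x, mg$groups)
  v <- s$pooledVar
  vmed <- stats::median(v)

  varOfVarGroup <- function(sub) {
    n <- ncol(sub)
    w <- (sub - rowMeans(sub))^2
    wbar <- rowMeans(w)
    n / (n - 1)^3 * rowSums((w - wbar)^2)
  }
  it <- as.character(mg$groups) == "tumor"
  vv1 <- varOfVarGroup(x[, it, drop = FALSE])
  vv2 <- varOfVarGroup(x[, !it, drop = FALSE])
  ## sampling variance of the pooled variance
  vv <- ((s$n1 - 1)^2 * vv1 + (s$n2 - 1)^2 * vv2) / (s$n1 + s$n2 - 2)^2

  denom <- sum((v - vmed)^2)
  lambda <- if (denom == 0) 1 else min(1, sum(vv) / denom)
  vstar <- lambda * vmed + (1 - lambda) * v
  t <- s$diff / sqrt(vstar * s$scale^2)
  p <- 2 * stats::pt(-abs(t), df = s$df)
  out <- data.frame(t = t, p = p, row.names = rownames(x))
  attr(out, "lambda") <- lambda
  out
}

#' Moderated (empirical Bayes) t-statistic
#'
#' Squeezes per-gene pooled variances toward a common prior value:
#' `s2_post = (d0 s0^2 + df s2) / (d0 + df)`, the prior df `d0` and scale
#' `s0^2` estimated by moment matching on `log s2` (trigamma inversion), as
#' in the standard empirical-Bayes linear-model framework; the estimation is
#' delegated to `limma::squeezeVar`. The statistic uses `d0 + df` degrees of
#' freedom; `d0 = Inf` gives the common-variance normal-theory limit.
#'
#' @inheritParams log2FoldChange
#' @param d0,s02 optional prior df and prior variance overriding estimation
#'   (`d0 = 0` reproduces the ordinary t exactly).
#' @return data.frame with columns `t`, `p`; attributes `d0` and `s02`.
#' @export
moderatedT <- function(g, groups = NULL, d0 = NULL, s02 = NULL) {
  mg <- .asMatrixGroups(g, groups)
  s <- .groupSummaries(mg$x, mg$groups)
  s2 <- s$pooledVar
  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, df = s$df)
    d0 <- sq$df.prior
    s02 <- sq$var.prior
    s2post <- sq$var.post
  } else {
    if (is.infinite(d0)) {
      if (is.null(s02)) s02 <- mean(s2)
      s2post <- rep(s02, length(s2))
    } else {
      if (is.null(s02)) s02 <- mean(s2)
      s2post <- (d0 * s02 + s$df * s2) / (d0 + s$df)
    }
  }
  t <- s$diff / sqrt(s2post * s$scale^2)
  dfTotal <- s$df + d0
  p <- if (is.infinite(dfTotal)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = dfTotal)
  out <- data.frame(t = t, p = p, row.names = rownames(mg$x))
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

## 0/0 (a flat gene: no spread, no difference) maps to d = 0
.safeD <- function(num, den) {
  out <- num / den
  out[den == 0] <- ifelse(num[den == 0] == 0, 0,
                          sign(num[den == 0]) * Inf)
  out
}

## SAM fudge factor: candidate s0 among the 0,5,...,100th percentiles of s;
## pick the one minimizing the coefficient of variation of the median
## absolute deviation of d across (up to) 100 quantile windows of s.
.samFudge <- function(diff, sdev) {
  cand <- unique(stats::quantile(sdev, seq(0, 1, by = 0.05), names = FALSE))
  nbin <- min(100L, max(1L, floor(length(sdev) / 5)))
  bins <- ceiling(rank(sdev, ties.method = "first") * nbin / length(sdev))
  cv <- vapply(cand, function(s0) {
    d <- .safeD(diff, sdev + s0)
    d[!is.finite(d)] <- 0
    mads <- tapply(d, bins, stats::mad)
    if (anyNA(mads) || length(mads) < 2L || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  ## too few genes for variance windows: fall back to the median spread
  if (!any(is.finite(cv))) return(stats::median(sdev))
  cand[which.min(cv)]
}

## enumerate or sample tumor-index sets for the permutation null
.samPermutations <- function(n, n1, B, seed) {
  total <- choose(n, n1)
  if (total < 20) {
    return(list(sets = utils::combn(n, n1), exact = TRUE))
  }
  set.seed(seed)
  obs <- seq_len(n1)
  sets <- matrix(0L, n1, B)
  b <- 0L
  while (b < B) {
    cand <- sort(sample.int(n, n1))
    if (identical(cand, obs)) next  # null permutations exclude the
    b <- b + 1L                     # observed labelling
    sets[, b] <- cand
  }
  list(sets = sets, exact = FALSE)
}

#' SAM statistic with permutation p-values
#'
#' The significance-analysis-of-microarrays statistic
#' `d = diff / (s + s0)` where `s` is the pooled standard error and the
#' fudge factor `s0` is chosen among the 0,5,...,100th percentiles of `s`
#' to minimize the coefficient of variation of `mad(d)` across quantile
#' windows of `s`. Two-sided p-values come from label permutations
#' (`nPermutations` draws distinct from the observed labelling, +1
#' pseudo-count in numerator and denominator); when fewer than 20 distinct
#' label splits exist, all of them are enumerated instead.
#'
#' @inheritParams log2FoldChange
#' @param nPermutations,seed permutation settings (see [deConfig()]).
#' @return data.frame with columns `d`, `p`; attribute `s0`.
#' @export
samStatistic <- function(g, groups = NULL, nPermutations = 1000L, seed = 1L) {
  mg <- .asMatrixGroups(g, groups)
  x <- mg$x
  grp <- as.character(mg$groups)
  s <- .groupSummaries(x, grp)
  sdev <- sqrt(s$pooledVar) * s$scale
  s0 <- .samFudge(s$diff, sdev)
  d <- .safeD(s$diff, sdev + s0)

  ## reorder columns tumor-first so the observed labelling is indices 1..n1
  ord <- c(which(grp == "tumor"), which(grp == "normal"))
  x <- x[, ord, drop = FALSE]
  n <- ncol(x); n1 <- s$n1; n2 <- s$n2
  perms <- .samPermutations(n, n1, nPermutations, seed)
  sets <- perms$sets
  B <- ncol(sets)

  ind <- matrix(0, n, B)
  ind[cbind(as.vector(sets), rep(seq_len(B), each = n1))] <- 1
  sum1 <- x %*% ind
  sum2 <- rowSums(x) - sum1
  m1 <- sum1 / n1; m2 <- sum2 / n2
  sq1 <- x^2 %*% ind
  sq2 <- rowSums(x^2) - sq1
  ssq <- pmax((sq1 - n1 * m1^2) + (sq2 - n2 * m2^2), 0)
  dPerm <- .safeD(m1 - m2, sqrt(ssq / s$df) * s$scale + s0)

  exceed <- rowSums(abs(dPerm) >= abs(d) - 1e-12)
  p <- if (perms$exact) exceed / B else (1 + exceed) / (1 + B)
  out <- data.frame(d = d, p = p, row.names = rownames(x))
  attr(out, "s0") <- s0
  attr(out, "exact") <- perms$exact
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, names preserved.
#' @export
adjustBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Consensus differential expression calls
#'
#' Combines the five rankers: a gene is significant under the fold-change
#' ranker when `|log2fc| >= fcThreshold` and under each statistic when its
#' BH-adjusted p is `<= alpha`. The consensus flag requires significance in
#' at least `mRequired` of the five methods plus an identical direction sign
#' across the four statistics' point estimates. The headline adjusted p per
#' gene is the maximum over the four statistics (the most conservative).
#'
#' @param log2fc named log2 fold changes.
#' @param tOrdinary,tShrink,tModerated,dSam the per-method data.frames from
#'   [ordinaryT()], [shrinkageT()], [moderatedT()], [samStatistic()], all on
#'   the same gene universe.
#' @param config a [deConfig()].
#' @return A `data.frame` (one row per gene) with the fold changes, the four
#'   statistics, raw and adjusted p-values, `n_methods_significant`,
#'   `consensus` and `direction` columns, ordered by headline adjusted p.
#' @export
consensusCalls <- function(log2fc, tOrdinary, tShrink, tModerated, dSam,
                           config = deConfig()) {
  genes <- names(log2fc)
  others <- list(tOrdinary, tShrink, tModerated, dSam)
  if (!all(vapply(others, function(o) setequal(rownames(o), genes),
                  logical(1))))
    stop("all five methods must be computed on the same gene universe")
  tOrdinary <- tOrdinary[genes, ]; tShrink <- tShrink[genes, ]
  tModerated <- tModerated[genes, ]; dSam <- dSam[genes, ]

  padj <- cbind(t_ordinary = adjustBH(tOrdinary$p),
                t_shrink = adjustBH(tShrink$p),
                t_moderated = adjustBH(tModerated$p),
                d_sam = adjustBH(dSam$p))
  sig <- cbind(fc = abs(log2fc) >= config$fcThreshold,
               padj <= config$alpha)
  nSig <- rowSums(sig)

  stats <- cbind(tOrdinary$t, tShrink$t, tModerated$t, dSam$d)
  sgn <- sign(stats)
  dirOK <- apply(sgn, 1L, function(r) {
    r <- r[r != 0]
    length(r) == 0 || all(r == r[1])
  })

  res <- data.frame(
    gene_id = genes,
    log2fc = unname(log2fc),
    signed_fc = unname(signedFoldChange(log2fc)),
    t_ordinary = tOrdinary$t, t_shrink = tShrink$t,
    t_moderated = tModerated$t, d_sam = dSam$d,
    p_t_ordinary = tOrdinary$p, p_t_shrink = tShrink$p,
    p_t_moderated = tModerated$p, p_d_sam = dSam$p,
    padj_t_ordinary = padj[, "t_ordinary"],
    padj_t_shrink = padj[, "t_shrink"],
    padj_t_moderated = padj[, "t_moderated"],
    padj_d_sam = padj[, "d_sam"],
    p_headline = apply(padj, 1L, max),
    n_methods_significant = as.integer(nSig),
    consensus = nSig >= config$mRequired & dirOK,
    direction = ifelse(log2fc >= 0, "up", "down"),
    row.names = genes, stringsAsFactors = FALSE)
  res[order(res$p_headline, -abs(res$log2fc), res$gene_id), ]
}

#' Run the full consensus differential expression analysis
#'
#' @param g a [GeneMatrix-class].
#' @param config a [deConfig()].
#' @return The consensus `data.frame` of [consensusCalls()].
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 100L))
#' gm <- collapseProbesToGenes(
#'   quantileNormalize(filterByDetection(sim$expression)), sim$mapping)
#' de <- runDiffExpr(gm, deConfig(nPermutations = 100L))
#' head(de[de$consensus, c("gene_id", "log2fc", "p_headline")])
#' @export
runDiffExpr <- function(g, config = deConfig()) {
  stopifnot(is(g, "GeneMatrix"))
  lfc <- log2FoldChange(g)
  consensusCalls(lfc,
                 tOrdinary = ordinaryT(g),
                 tShrink = shrinkageT(g),
                 tModerated = moderatedT(g),
                 dSam = samStatistic(g, nPermutations = config$nPermutations,
                                     seed = config$seed),
                 config = config)
}
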