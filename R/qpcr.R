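## qPCR relative quantification (delta-delta-CT against a housekeeping gene)
## and nonparametric group comparison.

#' Delta-delta-CT relative quantification
#'
#' Livak method: `dCT_s = CT_s,gene - CT_s,housekeeping`; `ddCT_s = dCT_s -
#' mean(dCT over normal samples)`; per-sample fold change `2^(-ddCT_s)`.
#' Group fold changes are summarized as mean +/- SEM on the linear scale.
#' By construction the normal group's log2 fold changes average zero
#' (geometric mean 1).
#'
#' @param t a [QPCRTable-class].
#' @param gene target gene id.
#' @return list with `perSample` (data.frame sample, group, dct, ddct, fc)
#'   and `summary` (per-group mean fold change and SEM).
#' @export
ddctFoldChange <- function(t, gene) {
  stopifnot(is(t, "QPCRTable"))
  ct <- ctValues(t)
  if (!gene %in% colnames(ct)) stop("gene not in the CT table: ", gene)
  grp <- sampleGroups(t)
  if (!any(grp == "normal")) stop("no normal (reference) samples")
  dct <- ct[, gene] - ct[, housekeepingGene(t)]
  ddct <- dct - mean(dct[grp == "normal"])
  fc <- 2^(-ddct)
  perSample <- data.frame(sample = rownames(ct), group = as.character(grp),
                          dct = dct, ddct = ddct, fc = fc,
                          stringsAsFactors = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- do.call(rbind, lapply(split(fc, grp), function(x)
    data.frame(mean_fc = mean(x), sem = sem(x), n = length(x))))
  summary$group <- rownames(summary)
  list(perSample = perSample, summary = summary)
}

## exact two-sided Mann-Whitney by enumeration of all C(n1+n2, n1) group
## assignments of the pooled observations (handles ties exactly); U counts
## pairs with x > y plus half the ties.
.mannWhitneyU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

.mannWhitneyExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  U <- .mannWhitneyU(x, y)
  mid <- n1 * n2 / 2
  splits <- utils::combn(n1 + n2, n1)
  devs <- apply(splits, 2L, function(ix)
    abs(.mannWhitneyU(pooled[ix], pooled[-ix]) - mid))
  p <- mean(devs >= abs(U - mid) - 1e-9)
  list(U = U, p = p, method = "exact enumeration")
}

#' Nonparametric group comparison of qPCR measurements
#'
#' Two-sided Mann-Whitney test of the per-sample fold changes (tumor vs
#' normal): exact by enumeration of all label assignments when both groups
#' have at most `exactMax` samples (ties handled exactly), otherwise the
#' normal approximation with tie correction. Optionally adds a Spearman
#' correlation against a paired covariate and a Fisher exact test on a
#' user-supplied 2x2 table.
#'
#' @param t a [QPCRTable-class].
#' @param gene target gene id.
#' @param covariate optional numeric covariate (one value per sample, in CT
#'   table order) for the Spearman correlation.
#' @param table2x2 optional 2x2 contingency matrix for Fisher's exact test.
#' @param exactMax maximum per-group size for the exact Mann-Whitney
#'   (default 8).
#' @return list with `U`, `p_mw`, `mw_method`, and optional `rho`, `p_sp`,
#'   `fisher_p`.
#' @export
groupCompare <- function(t, gene, covariate = NULL, table2x2 = NULL,
                         exactMax = 8L) {
  stopifnot(is(t, "QPCRTable"))
  grp <- sampleGroups(t)
  fc <- ddctFoldChange(t, gene)$perSample$fc
  x <- fc[grp == "tumor"]; y <- fc[grp == "normal"]
  if (length(x) < 2L || length(y) < 2L)
    stop("at least 2 samples per group are required")
  if (length(x) <= exactMax && length(y) <= exactMax) {
    mw <- .mannWhitneyExact(x, y)
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    mw <- list(U = unname(wt$statistic), p = wt$p.value,
               method = "normal approximation")
  }
  out <- list(U = mw$U, p_mw = mw$p, mw_method = mw$method)
  if (!is.null(covariate)) {
    sp <- stats::cor.test(fc, covariate, method = "spearman", exact = FALSE)
    out$rho <- unname(sp$estimate)
    out$p_sp <- sp$p.value
  }
  if (!is.null(table2x2))
    out$fisher_p <- stats::fisher.test(table2x2)$p.value
  out
}
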