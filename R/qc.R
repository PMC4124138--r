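## Quality control and normalization: detection-call filtering, quantile
## normalization on log2(x + 1), KS-based whole-array outlier detection and
## probe -> gene collapsing.

#' Filter probes by detection calls
#'
#' Retains probes whose present-call count is strictly greater than
#' `minFraction` of the samples (a probe present in exactly half of the
#' arrays is dropped).
#'
#' @param m an [ExpressionMatrix-class].
#' @param minFraction required present fraction (default 0.5).
#' @return The filtered [ExpressionMatrix-class]; probe order is preserved
#'   and the in/out probe counts are stored in `metadata()`.
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 50L))
#' filt <- filterByDetection(sim$expression)
#' @export
filterByDetection <- function(m, minFraction = 0.5) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (nrow(m) == 0L) stop("empty expression matrix")
  calls <- detectionCalls(m)
  keep <- rowSums(calls) > minFraction * ncol(calls)
  out <- m[keep, ]
  metadata(out)$nProbesIn <- nrow(m)
  metadata(out)$nProbesRetained <- sum(keep)
  out
}

## core: columns of log2(x + 1) (or x as-is) are replaced by cross-column
## rank means; ties within a column get the mean of their ranks' reference
## values.
.quantileNormalizeMatrix <- function(x, log2transform = TRUE) {
  v <- if (log2transform) log2(x + 1) else x
  if (ncol(v) == 1L) {
    warning("single-sample matrix: returning the (log2) values unchanged")
    return(v)
  }
  ref <- rowMeans(apply(v, 2L, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    r <- numeric(length(col))
    r[order(col)] <- ref
    out[, j] <- stats::ave(r, match(col, col), FUN = mean)
  }
  out
}

#' Quantile normalization
#'
#' Replaces each column's sorted values by the across-column means of the
#' order statistics of `log2(x + 1)`, forcing all columns to share one value
#' multiset. Tied values within a column receive the mean of the reference
#' values at their ranks.
#'
#' @param m an [ExpressionMatrix-class] or plain matrix.
#' @param log2transform apply `log2(x + 1)` first (default TRUE; set FALSE
#'   for values already on a log scale).
#' @return Object of the same class; for an [ExpressionMatrix-class] the
#'   `exprs` assay now holds normalized log2-scale values and
#'   `metadata()$normalized` is set.
#' @export
quantileNormalize <- function(m, log2transform = TRUE) {
  if (is(m, "ExpressionMatrix")) {
    norm <- .quantileNormalizeMatrix(intensities(m), log2transform)
    assays(m)$exprs <- norm
    metadata(m)$normalized <- TRUE
    return(m)
  }
  .quantileNormalizeMatrix(as.matrix(m), log2transform)
}

## D_a = sup_x |F_a(x) - F_pooled(x)| where F_pooled pools all arrays
## (including a). Both empirical CDFs only jump at pooled data points, so
## the supremum is attained there.
.ksToPooled <- function(x) {
  n <- ncol(x)
  pooled <- sort(as.vector(x))
  pts <- unique(pooled)
  Fpool <- cumsum(tabulate(match(pooled, pts))) / length(pooled)
  D <- vapply(seq_len(n), function(j) {
    Fa <- findInterval(pts, sort(x[, j])) / nrow(x)
    max(abs(Fa - Fpool))
  }, numeric(1))
  setNames(D, colnames(x))
}

#' Kolmogorov-Smirnov array outlier detection
#'
#' Scores each array by the KS statistic `D` between its intensity
#' distribution and the distribution of the data pooled over all arrays
#' (the array under test included). Arrays are flagged when `D` exceeds the
#' Tukey upper fence `Q3 + 1.5 IQR` of the `D` values.
#'
#' @param m an [ExpressionMatrix-class] (at least 3 samples).
#' @return A [QCReport-class].
#' @export
ksOutlierDetection <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  D <- .ksToPooled(intensities(m))
  q <- stats::quantile(D, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  new("QCReport",
      nProbesIn = metadata(m)$nProbesIn %||% NA_integer_,
      nProbesRetained = metadata(m)$nProbesRetained %||% NA_integer_,
      ksStat = D, outliers = names(D)[D > fence], threshold = fence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse probes to genes
#'
#' Drops probes without a gene mapping and averages the (log2-scale) values
#' of probes mapping to the same gene, per sample.
#'
#' @param m a normalized [ExpressionMatrix-class] (log2 scale, i.e. after
#'   [quantileNormalize()]).
#' @param mapping data.frame with columns `probe_id` and `gene_id` (NA gene
#'   = unmappable).
#' @return A [GeneMatrix-class].
#' @export
collapseProbesToGenes <- function(m, mapping) {
  stopifnot(is(m, "ExpressionMatrix"),
            all(c("probe_id", "gene_id") %in% colnames(mapping)))
  mapping <- mapping[!is.na(mapping$gene_id), , drop = FALSE]
  mapping <- mapping[mapping$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(mapping) == 0L) {
    warning("empty probe-to-gene mapping: returning an empty GeneMatrix")
    empty <- matrix(numeric(), 0, ncol(m),
                    dimnames = list(NULL, colnames(m)))
    return(GeneMatrix(empty, sampleGroups(m)))
  }
  x <- intensities(m)[mapping$probe_id, , drop = FALSE]
  sums <- rowsum(x, group = mapping$gene_id)
  counts <- as.vector(table(mapping$gene_id)[rownames(sums)])
  GeneMatrix(sums / counts, sampleGroups(m))
}
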