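## Cross-dataset co-analysis: fold-change correlation, shared DE genes,
## top-k ranking overlap and curated-list intersections.

#' Correlate fold changes of two studies
#'
#' Pearson (default) correlation of the log2 fold changes over the common
#' gene universe, with the two-sided parametric p-value of the t transform.
#'
#' @param a,b consensus data.frames from [runDiffExpr()].
#' @param method "pearson" (default) or "spearman".
#' @return list with `n` (common genes), `r` and `p`.
#' @export
correlateFoldChanges <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(a$gene_id, b$gene_id)
  if (length(common) < 3L) stop("fewer than 3 common genes")
  ct <- stats::cor.test(a[common, "log2fc"], b[common, "log2fc"],
                        method = method, exact = FALSE)
  list(n = length(common), r = unname(ct$estimate), p = ct$p.value)
}

#' Shared consensus DE genes between two studies
#'
#' Intersection of the consensus-significant gene sets; the headline
#' fraction uses the smaller set as denominator, the Jaccard coefficient is
#' also reported.
#'
#' @param a,b consensus data.frames from [runDiffExpr()].
#' @return list with `shared` (gene vector), `n_a`, `n_b`, `fraction`
#'   (min-based) and `jaccard`.
#' @export
sharedDEGenes <- function(a, b) {
  sa <- a$gene_id[a$consensus]
  sb <- b$gene_id[b$consensus]
  shared <- intersect(sa, sb)
  dmin <- min(length(sa), length(sb))
  duni <- length(union(sa, sb))
  list(shared = shared, n_a = length(sa), n_b = length(sb),
       fraction = if (dmin == 0) 0 else length(shared) / dmin,
       jaccard = if (duni == 0) 0 else length(shared) / duni)
}

## deterministic DE ranking: headline adjusted p ascending, then |log2fc|
## descending, then gene id
.deRanking <- function(de) {
  de$gene_id[order(de$p_headline, -abs(de$log2fc), de$gene_id)]
}

#' Jaccard overlap of the top-k ranked genes
#'
#' Ranks both studies by headline adjusted p (ties broken by |log2 fold
#' change| descending, then gene id) and returns the Jaccard coefficient of
#' the two top-`k` sets.
#'
#' @param a,b consensus data.frames from [runDiffExpr()].
#' @param k size of the top lists (default 1000).
#' @return Jaccard coefficient in \[0, 1\].
#' @export
topkJaccard <- function(a, b, k = 1000L) {
  if (k > nrow(a) || k > nrow(b))
    stop("k exceeds the ranked universe")
  ta <- utils::head(.deRanking(a), k)
  tb <- utils::head(.deRanking(b), k)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Intersect consensus DE genes with a curated list
#'
#' Case-insensitive symbol matching (after whitespace stripping) of
#' consensus differentially expressed genes of the requested direction
#' against a user-supplied curated list (e.g. COSMIC cancer genes or
#' enteroendocrine transcription factors).
#'
#' @param de consensus data.frame from [runDiffExpr()].
#' @param curated character vector of gene symbols.
#' @param direction "up", "down" or "any".
#' @return Character vector of matching consensus genes (original casing).
#' @export
intersectCuratedList <- function(de, curated,
                                 direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (!length(curated)) stop("empty curated list")
  norm <- function(x) toupper(trimws(x))
  keep <- de$consensus
  if (direction != "any") keep <- keep & de$direction == direction
  hits <- de$gene_id[keep][norm(de$gene_id[keep]) %in% norm(curated)]
  unique(hits)
}
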