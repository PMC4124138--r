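## Term over-representation (hypergeometric, classic Fisher-style) and
## model-based gene-set enrichment (Bayesian on/off set activations).

#' Hypergeometric term over-representation
#'
#' For each term with at least `minSize` genes in the universe, tests the
#' upper-tail hypergeometric probability `P(X >= k)` of observing `k` DE
#' genes among the term's `K` universe genes, given `n` DE genes out of `N`.
#' BH adjustment is applied within each namespace (BP/CC/MF/pathway/...)
#' because the namespaces are enriched separately.
#'
#' @param de character vector of differentially expressed genes (must be a
#'   subset of `universe`).
#' @param universe character vector of all analyzed genes.
#' @param gs a [GeneSetList-class].
#' @param minSize terms with fewer assigned (universe) genes are excluded
#'   (default 10).
#' @return data.frame with columns `term_id`, `namespace`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, sorted by `p`.
#' @export
hypergeometricEnrichment <- function(de, universe, gs, minSize = 10L) {
  stopifnot(is(gs, "GeneSetList"))
  if (length(universe) == 0L) stop("empty universe")
  if (length(de) == 0L) stop("empty DE gene set")
  if (!all(de %in% universe)) stop("de must be a subset of the universe")
  de <- unique(de); universe <- unique(universe)
  N <- length(universe); n <- length(de)

  rows <- lapply(names(gs@sets), function(id) {
    members <- intersect(gs@sets[[id]], universe)
    K <- length(members)
    if (K < minSize) return(NULL)
    k <- length(intersect(members, de))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, namespace = unname(gs@namespace[id]),
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric()))
  res$p_adj <- stats::ave(res$p, res$namespace, FUN = adjustBH)
  res[order(res$p, res$term_id), ]
}

## log-likelihood pieces of the set-activation model:
## P(O=1|H=0)=alpha, P(O=0|H=0)=1-alpha, P(O=1|H=1)=1-beta, P(O=0|H=1)=beta
.mgsaGeneLogLik <- function(obs, alpha, beta) {
  cbind(h0 = ifelse(obs, log(alpha), log(1 - alpha)),
        h1 = ifelse(obs, log(1 - beta), log(beta)))
}

.mgsaExact <- function(member, obs, alpha, beta, prior) {
  S <- ncol(member)
  G <- nrow(member)
  ll <- .mgsaGeneLogLik(obs, alpha, beta)
  nStates <- 2^S
  logw <- numeric(nStates)
  onBits <- matrix(0, nStates, S)
  chunk <- 2^14
  states <- as.matrix(expand.grid(rep(list(0:1), S)))
  for (start in seq(1, nStates, by = chunk)) {
    idx <- start:min(start + chunk - 1, nStates)
    z <- states[idx, , drop = FALSE]
    cover <- member %*% t(z) > 0           # G x |idx|
    logLik <- colSums(ifelse(cover, ll[, "h1"], ll[, "h0"]))
    k <- rowSums(z)
    logw[idx] <- logLik + k * log(prior) + (S - k) * log(1 - prior)
    onBits[idx, ] <- z
  }
  w <- exp(logw - max(logw))
  as.vector(crossprod(onBits, w) / sum(w))
}

.mgsaMCMC <- function(member, obs, alpha, beta, prior, nSweeps, burnIn,
                      seed) {
  set.seed(seed)
  S <- ncol(member)
  ll <- .mgsaGeneLogLik(obs, alpha, beta)
  z <- rep(FALSE, S)
  cover <- integer(nrow(member))
  logPriorOn <- log(prior) - log(1 - prior)
  hits <- numeric(S)
  nBurn <- floor(burnIn * nSweeps)
  memberIdx <- lapply(seq_len(S), function(t) which(member[, t] > 0))

  for (sweep in seq_len(nSweeps)) {
    t <- sample.int(S, 1L)
    idx <- memberIdx[[t]]
    if (z[t]) {                      # propose switching OFF
      newCover <- cover[idx] - 1L
      flip <- newCover == 0L
      delta <- sum(ll[idx[flip], "h0"] - ll[idx[flip], "h1"]) - logPriorOn
    } else {                         # propose switching ON
      flip <- cover[idx] == 0L
      delta <- sum(ll[idx[flip], "h1"] - ll[idx[flip], "h0"]) + logPriorOn
    }
    if (delta >= 0 || log(stats::runif(1)) < delta) {
      if (z[t]) cover[idx] <- cover[idx] - 1L
      else cover[idx] <- cover[idx] + 1L
      z[t] <- !z[t]
    }
    if (sweep > nBurn) hits <- hits + z
  }
  hits / (nSweeps - nBurn)
}

#' Model-based gene-set enrichment (Bayesian set activation)
#'
#' Generative model: each set carries a hidden activation `Z_t ~
#' Bernoulli(prior)`; a gene is hidden-on (`H_g = 1`) iff it belongs to at
#' least one active set; the observed DE label arises with false-positive
#' rate `alpha` (`P(O=1|H=0)`) and false-negative rate `beta`
#' (`P(O=0|H=1)`). Posterior activation probabilities `P(Z_t = 1 | O)` are
#' computed by exact enumeration of all `2^S` states when `S <= exactLimit`,
#' and otherwise by a Metropolis sampler toggling one random set per sweep.
#'
#' @param de,universe DE genes and analyzed universe (`de` a subset).
#' @param gs a [GeneSetList-class].
#' @param alpha,beta false-positive/false-negative rates, in (0, 0.5).
#' @param prior set-activation prior probability.
#' @param nSweeps MCMC sweeps (default 1e5; 10% burn-in).
#' @param burnIn burn-in fraction.
#' @param seed RNG seed for the sampler.
#' @param exactLimit maximum set count for exact enumeration (default 20).
#' @return An [MgsaResult-class].
#' @export
mgsa <- function(de, universe, gs, alpha = 0.1, beta = 0.25, prior = 0.05,
                 nSweeps = 1e5, burnIn = 0.1, seed = 1L, exactLimit = 20L) {
  stopifnot(is(gs, "GeneSetList"))
  if (alpha <= 0 || alpha >= 0.5 || beta <= 0 || beta >= 0.5)
    stop("alpha and beta must lie in (0, 0.5)")
  if (!all(de %in% universe)) stop("de must be a subset of the universe")
  ids <- names(gs@sets)
  if (length(ids) == 0L)
    return(new("MgsaResult", posterior = setNames(numeric(0), character(0)),
               alpha = alpha, beta = beta, prior = prior, method = "exact",
               nSweeps = NA_real_, seed = NA_real_))

  universe <- unique(universe)
  ## genes in no set contribute a constant factor; restrict to covered genes
  covered <- intersect(universe, unique(unlist(gs@sets)))
  member <- vapply(gs@sets,
                   function(s) as.numeric(covered %in% s), numeric(length(covered)))
  member <- matrix(member, nrow = length(covered), ncol = length(ids),
                   dimnames = list(covered, ids))
  obs <- covered %in% de

  if (length(ids) <= exactLimit) {
    post <- .mgsaExact(member, obs, alpha, beta, prior)
    method <- "exact"; sweeps <- NA_real_; sd <- NA_real_
  } else {
    post <- .mgsaMCMC(member, obs, alpha, beta, prior, nSweeps, burnIn, seed)
    method <- "mcmc"; sweeps <- nSweeps; sd <- seed
  }
  new("MgsaResult", posterior = setNames(post, ids), alpha = alpha,
      beta = beta, prior = prior, method = method, nSweeps = sweeps,
      seed = as.numeric(sd))
}

#' Overlap of two enrichment results
#'
#' Compares the significant term sets (`p_adj <= alpha`) of two enrichment
#' tables. Both the min-based overlap `|A ∩ B| / min(|A|, |B|)` (the
#' headline) and the Jaccard coefficient are reported; empty significant
#' sets give 0 by convention.
#'
#' @param a,b data.frames from [hypergeometricEnrichment()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with `sig_a`, `sig_b`, `shared`, `overlap` (min-based) and
#'   `jaccard`.
#' @export
enrichmentOverlap <- function(a, b, alpha = 0.05) {
  sa <- a$term_id[a$p_adj <= alpha]
  sb <- b$term_id[b$p_adj <= alpha]
  shared <- intersect(sa, sb)
  denomMin <- min(length(sa), length(sb))
  denomUnion <- length(union(sa, sb))
  list(sig_a = sa, sig_b = sb, shared = shared,
       overlap = if (denomMin == 0) 0 else length(shared) / denomMin,
       jaccard = if (denomUnion == 0) 0 else length(shared) / denomUnion)
}
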