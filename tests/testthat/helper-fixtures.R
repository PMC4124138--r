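# Shared fixtures and independent oracles used across test files.

# small study configuration for fast simulation-based tests
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(nGenes = 300L, ppiNodes = 80L, plantedModuleSize = 10L,
         nGeneSets = 12L, nEnrichedSets = 3L, seed = seed),
    list(...))
  do.call(simConfig, args)
}

# toy gene matrix from explicit per-group values
toyGeneMatrix <- function(tumor, normal, genes = NULL) {
  x <- cbind(tumor, normal)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(x)))
  rownames(x) <- genes
  colnames(x) <- c(paste0("T", seq_len(ncol(tumor))),
                   paste0("N", seq_len(ncol(normal))))
  GeneMatrix(x, rep(c("tumor", "normal"), c(ncol(tumor), ncol(normal))))
}

# brute-force BH step-up: p_(i) * n / i with cumulative minimum from the top
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force KS statistic of column j against the pooled data, via ecdf
# functions evaluated on the pooled grid
ksOracle <- function(x, j) {
  Fa <- stats::ecdf(x[, j])
  Fp <- stats::ecdf(as.vector(x))
  grid <- sort(unique(as.vector(x)))
  max(abs(Fa(grid) - Fp(grid)))
}

# exhaustive maximum-weight shortest path: enumerate all shortest paths and
# apply the weight-then-lexicographic tie-break
pathOracle <- function(g, w, u, v) {
  asp <- tryCatch(
    suppressWarnings(igraph::all_shortest_paths(g, u, v)$res),
    error = function(e) list())
  if (!length(asp)) return(NULL)
  paths <- lapply(asp, names)
  Ws <- vapply(paths, function(p) sum(w[p]), numeric(1))
  best <- paths[abs(Ws - max(Ws)) < 1e-9]
  keys <- vapply(best, paste, "", collapse = "\r")
  list(path = best[[order(keys)[1]]], W = max(Ws))
}

# enumerate all set partitions of a vector (for brute-force modularity)
allPartitions <- function(items) {
  if (length(items) == 1L) return(list(list(items)))
  rest <- allPartitions(items[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(items[1], q[[k]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(items[1]), p)
  }
  out
}

# modularity of a node->community assignment, straight from the definition
modularityOracle <- function(g, membership) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  intra <- sum(membership[el[, 1]] == membership[el[, 2]])
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    nodes <- names(membership)[membership == c]
    ec <- sum(membership[el[, 1]] == c & membership[el[, 2]] == c)
    dc <- sum(deg[nodes])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# exact MGSA posteriors by direct loop over all activation states
mgsaOracle <- function(sets, universe, de, alpha, beta, prior) {
  S <- length(sets)
  ids <- names(sets)
  post <- setNames(numeric(S), ids)
  total <- 0
  for (state in 0:(2^S - 1)) {
    z <- as.logical(bitwAnd(state, 2^(0:(S - 1))))
    active <- unique(unlist(sets[z]))
    w <- prod(ifelse(z, prior, 1 - prior))
    for (gn in universe) {
      h <- gn %in% active
      o <- gn %in% de
      w <- w * if (h) { if (o) 1 - beta else beta } else {
        if (o) alpha else 1 - alpha }
    }
    total <- total + w
    post[z] <- post[z] + w
  }
  post / total
}
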