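## Node-weighted network analysis: weight assignment, maximum-weight
## shortest-path extraction between seed genes, greedy modularity
## communities, Jaccard community similarity, and secretory-annotation
## subnetworks.

#' Assign differential expression weights to network nodes
#'
#' Every node mapped in the DE table gets weight `-log10(p)` of its headline
#' adjusted p-value (the maximum over the four statistics; configurable to
#' any p column); unmapped nodes get weight 0. Consensus genes are flagged
#' as seed nodes.
#'
#' @param graph an igraph (or [WeightedGraph-class]) with gene-symbol vertex
#'   names.
#' @param de the consensus data.frame from [runDiffExpr()].
#' @param pColumn which p-value column feeds the weights (default
#'   `"p_headline"`, the adjusted headline p).
#' @return A [WeightedGraph-class].
#' @export
assignNodeWeights <- function(graph, de, pColumn = "p_headline") {
  g <- if (is(graph, "WeightedGraph")) graph@graph else graph
  p <- setNames(de[[pColumn]], de$gene_id)
  if (any(p <= 0)) stop("p-values must be positive to take -log10")
  WeightedGraph(g, weights = -log10(p),
                seeds = de$gene_id[de$consensus])
}

## Max-weight shortest path between u and v given precomputed hop distances
## from u and v and an adjacency list. Returns NULL when disconnected.
## Among all minimum-hop paths the node-weight sum (endpoints included) is
## maximized; remaining ties break to the lexicographically smallest node
## sequence.
.bestPath <- function(adj, w, du, dv, u, v) {
  L <- du[[v]]
  if (!is.finite(L)) return(NULL)
  on <- names(du)[is.finite(du) & is.finite(dv) & du + dv == L]
  ## suffix[x] = best achievable node-weight sum from x to v along
  ## shortest-path continuations
  suffix <- setNames(rep(-Inf, length(on)), on)
  for (x in on[order(du[on], decreasing = TRUE)]) {
    if (x == v) { suffix[x] <- w[[v]]; next }
    succ <- intersect(adj[[x]], on)
    succ <- succ[du[succ] == du[[x]] + 1]
    suffix[x] <- w[[x]] + max(suffix[succ])
  }
  ## greedy reconstruction: smallest node id among weight-optimal successors
  path <- u
  cur <- u
  while (cur != v) {
    succ <- intersect(adj[[cur]], on)
    succ <- succ[du[succ] == du[[cur]] + 1]
    best <- succ[abs(suffix[succ] - max(suffix[succ])) < 1e-9]
    cur <- sort(best)[1]
    path <- c(path, cur)
  }
  list(path = path, W = unname(suffix[u]))
}

#' Maximum-weight shortest path between two nodes
#'
#' Among all minimum-hop paths between `u` and `v`, returns the one whose
#' sum of node weights (both endpoints included) is largest, computed by
#' dynamic programming over the breadth-first layered graph. Ties are broken
#' deterministically to the lexicographically smallest node sequence.
#'
#' @param g a [WeightedGraph-class].
#' @param u,v distinct node names.
#' @return list with `path` (node sequence) and `W` (node-weight sum), or
#'   `NULL` when `u` and `v` are disconnected.
#' @export
maxWeightShortestPath <- function(g, u, v) {
  stopifnot(is(g, "WeightedGraph"))
  if (u == v) stop("u and v must differ")
  ig <- g@graph
  nm <- igraph::V(ig)$name
  if (!all(c(u, v) %in% nm)) stop("u and v must be graph nodes")
  adj <- lapply(igraph::as_adj_list(ig), function(x) nm[as.integer(x)])
  names(adj) <- nm
  d <- igraph::distances(ig, v = c(u, v))
  du <- setNames(d[1, ], colnames(d)); dv <- setNames(d[2, ], colnames(d))
  .bestPath(adj, nodeWeights(g), du, dv, u, v)
}

#' Extract the seed/linker subnetwork
#'
#' For every unordered pair of seed nodes in the same connected component,
#' computes the maximum-weight shortest path; the subnetwork is the union of
#' all selected paths' nodes and consecutive-pair edges. Non-seed nodes on a
#' selected path are recorded as linkers. Seed pairs in different components
#' are skipped and reported.
#'
#' @param g a [WeightedGraph-class] with at least 2 seed nodes.
#' @param seeds optional override of the seed node set.
#' @return A [Subnetwork-class].
#' @export
extractSubnetwork <- function(g, seeds = seedNodes(g)) {
  stopifnot(is(g, "WeightedGraph"))
  ig <- g@graph
  nm <- igraph::V(ig)$name
  seeds <- intersect(seeds, nm)
  if (length(seeds) < 2L) stop("at least 2 seed nodes are required")
  seeds <- sort(seeds)
  w <- nodeWeights(g)
  adj <- lapply(igraph::as_adj_list(ig), function(x) nm[as.integer(x)])
  names(adj) <- nm
  comp <- igraph::components(ig)$membership
  dmat <- igraph::distances(ig, v = seeds)

  records <- list()
  skipped <- list()
  nodes <- character()
  edges <- matrix(character(), 0, 2)
  for (i in seq_len(length(seeds) - 1L)) {
    for (j in (i + 1L):length(seeds)) {
      u <- seeds[i]; v <- seeds[j]
      if (comp[[u]] != comp[[v]]) {
        skipped[[length(skipped) + 1L]] <- c(u, v)
        next
      }
      du <- dmat[u, ]; dv <- dmat[v, ]
      rec <- .bestPath(adj, w, du, dv, u, v)
      records[[paste(u, v, sep = "|")]] <- rec
      nodes <- union(nodes, rec$path)
      if (length(rec$path) > 1L)
        edges <- rbind(edges, cbind(rec$path[-length(rec$path)],
                                    rec$path[-1]))
    }
  }
  edges <- unique(t(apply(edges, 1L, sort)))
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2)
  sub <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes)))
  igraph::V(sub)$weight <- unname(w[igraph::V(sub)$name])
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% seeds
  skippedDf <- if (length(skipped))
    data.frame(u = vapply(skipped, `[`, "", 1),
               v = vapply(skipped, `[`, "", 2))
  else data.frame(u = character(), v = character())
  new("Subnetwork", graph = sub,
      seeds = intersect(seeds, nodes),
      linkers = setdiff(nodes, seeds),
      pathRecords = records, skippedPairs = skippedDf,
      nodeInfo = data.frame(node = sort(nodes),
                            status = ifelse(sort(nodes) %in% seeds,
                                            "seed", "linker")))
}

## modularity of a membership vector on an igraph, by the e_c/m - (d_c/2m)^2
## formula
.modularity <- function(ig, membership) {
  m <- igraph::ecount(ig)
  el <- igraph::as_edgelist(ig, names = TRUE)
  cu <- membership[el[, 1]]; cv <- membership[el[, 2]]
  eIntra <- tapply(cu == cv, cu, sum)
  deg <- igraph::degree(ig)
  dc <- tapply(deg[names(membership)], membership, sum)
  ec <- setNames(rep(0, length(dc)), names(dc))
  ec[names(eIntra)] <- eIntra
  sum(ec / m - (dc / (2 * m))^2)
}

#' Greedy modularity community detection
#'
#' Agglomerative modularity maximization: starting from singleton
#' communities, repeatedly merges the community pair with the largest
#' modularity gain until no merge has positive gain. Ties break to the
#' smallest community identifiers (communities are identified by their
#' smallest member in vertex-name order), making the partition
#' deterministic.
#'
#' @param g an igraph or [WeightedGraph-class] with at least one edge.
#' @return A [CommunityPartition-class].
#' @export
detectCommunities <- function(g) {
  ig <- if (is(g, "WeightedGraph")) g@graph else g
  if (igraph::ecount(ig) == 0L) stop("community detection needs edges")
  nm <- sort(igraph::V(ig)$name)
  n <- length(nm)
  m <- igraph::ecount(ig)
  el <- igraph::as_edgelist(ig, names = TRUE)
  iu <- match(el[, 1], nm); iv <- match(el[, 2], nm)

  ## edge-end bookkeeping: e[i, i] = intra-edge fraction of community i,
  ## off-diagonal e[i, j] = half the fraction of edges between i and j, so
  ## a_i = rowSums(e) = d_i / 2m, Q = sum(diag(e) - a^2) and the merge gain
  ## is dQ_ij = 2 (e_ij - a_i a_j)
  e <- matrix(0, n, n)
  for (k in seq_len(m)) {
    e[iu[k], iv[k]] <- e[iu[k], iv[k]] + 1 / (2 * m)
    e[iv[k], iu[k]] <- e[iv[k], iu[k]] + 1 / (2 * m)
  }
  a <- rowSums(e)                   # degree fraction per community
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))

  repeat {
    ## dQ_ij = 2 (e_ij - a_i a_j) for connected active pairs
    idx <- which(active)
    if (length(idx) < 2L) break
    dq <- 2 * (e[idx, idx, drop = FALSE] -
                 outer(a[idx], a[idx]))
    conn <- e[idx, idx, drop = FALSE] > 0
    dq[!conn] <- -Inf
    diag(dq) <- -Inf
    best <- max(dq)
    if (best <= 1e-12) break
    hit <- which(dq == best, arr.ind = TRUE)
    ## ties: smallest community ids (row, then col)
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE]
    i <- idx[min(hit[1, ])]; j <- idx[max(hit[1, ])]
    ## merge j into i
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    a[i] <- a[i] + a[j]
    e[j, ] <- 0; e[, j] <- 0; a[j] <- 0
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer()
  }

  membership <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!length(members[[i]])) next
    cid <- cid + 1L
    membership[members[[i]]] <- cid
  }
  names(membership) <- nm
  new("CommunityPartition", membership = membership,
      Q = .modularity(ig, membership))
}

#' Jaccard similarity between two community partitions
#'
#' `J(A, B) = |A ∩ B| / |A ∪ B|` for every community pair across the two
#' partitions: 0 for disparate and 1 for identical communities.
#'
#' @param a,b [CommunityPartition-class] objects.
#' @return Numeric matrix (communities of `a` x communities of `b`).
#' @export
communitySimilarity <- function(a, b) {
  stopifnot(is(a, "CommunityPartition"), is(b, "CommunityPartition"))
  ca <- communityList(a); cb <- communityList(b)
  if (!length(ca) || !length(cb)) stop("empty partition")
  out <- matrix(0, length(ca), length(cb),
                dimnames = list(paste0("A", names(ca)),
                                paste0("B", names(cb))))
  for (i in seq_along(ca))
    for (j in seq_along(cb))
      out[i, j] <- length(intersect(ca[[i]], cb[[j]])) /
        length(union(ca[[i]], cb[[j]]))
  out
}

#' Secretory-annotation subnetwork
#'
#' Selects the subnetwork nodes annotated to any of the given terms (e.g.
#' the serotonin-metabolism, substance-P-signaling and secretion GO terms)
#' together with their direct neighbors within the subnetwork, labeling each
#' node "annotated" or "neighbor".
#'
#' @param sub a [Subnetwork-class].
#' @param gs a [GeneSetList-class] carrying the annotation terms.
#' @param termIds term identifiers to extract; missing terms are skipped
#'   with a warning.
#' @return A [Subnetwork-class] induced on the selected nodes, with
#'   `nodeInfo` holding the annotated/neighbor status.
#' @export
secretorySubnetwork <- function(sub, gs, termIds) {
  stopifnot(is(sub, "Subnetwork"), is(gs, "GeneSetList"))
  missing <- setdiff(termIds, names(gs@sets))
  if (length(missing))
    warning("terms not in the collection (skipped): ",
            paste(missing, collapse = ", "))
  termIds <- setdiff(termIds, missing)
  annotGenes <- unique(unlist(gs@sets[termIds]))
  ig <- sub@graph
  nodes <- igraph::V(ig)$name
  annotated <- intersect(nodes, annotGenes)
  if (!length(annotated)) {
    empty <- igraph::make_empty_graph(0, directed = FALSE)
    return(new("Subnetwork", graph = empty, seeds = character(),
               linkers = character(),
               nodeInfo = data.frame(node = character(),
                                     status = character())))
  }
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(ig, annotated), function(x) nodes[as.integer(x)])))
  keep <- union(annotated, setdiff(nbrs, annotated))
  out <- igraph::induced_subgraph(ig, keep)
  outNodes <- igraph::V(out)$name
  info <- data.frame(node = outNodes,
                     status = ifelse(outNodes %in% annotated,
                                     "annotated", "neighbor"))
  new("Subnetwork", graph = out,
      seeds = intersect(sub@seeds, outNodes),
      linkers = intersect(sub@linkers, outNodes),
      nodeInfo = info)
}
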