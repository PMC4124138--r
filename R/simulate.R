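## Synthetic-data generators. Each artifact draws from its own RNG stream
## derived from the master seed (expression +0, network +1, gene sets +2,
## qPCR +3) so that regenerating one artifact never perturbs the others.

.streamSeed <- function(config, offset) {
  (config@seed + offset * 10007L) %% .Machine$integer.max
}

#' Simulate a two-group probe-level expression study
#'
#' Probe intensities are generated as
#' `2^(N(baselineLog2Mean, baselineLog2Sd) + group effect + N(0, noiseSd))`:
#' log2-scale Gaussians exponentiated to the linear scale, so the pipeline's
#' log2 transform is their exact inverse. Planted differentially expressed
#' genes shift the tumor group by +/- `deLog2FC`. A `backgroundFraction` of
#' probes (always including unmappable probes, never probes of planted
#' genes) sits 3 log2 units below baseline and receives present calls with
#' `detectProbBackground`; all other probes use `detectProbExpressed`.
#' Outlier arrays are shifted wholesale by `outlierShift` log2 units.
#'
#' @param config a [SimConfig-class].
#' @param truth optional [SyntheticTruth-class] whose planted DE genes are
#'   reused (for simulating a second dataset of the same biology).
#' @return A list with elements `expression` ([ExpressionMatrix-class]),
#'   `mapping` (data.frame `probe_id`, `gene_id`; NA for unmappable probes)
#'   and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 100L, seed = 3L))
#' dim(intensities(sim$expression))
#' @export
simulateExpression <- function(config, truth = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@nTumor < 2L || config@nNormal < 2L)
    stop("at least 2 samples per group are required")
  set.seed(.streamSeed(config, 0L))

  genes <- sprintf("G%05d", seq_len(config@nGenes))
  counts <- sample(as.integer(names(config@probesPerGene)), config@nGenes,
                   replace = TRUE, prob = config@probesPerGene)
  probeGene <- rep(genes, counts)
  nMapped <- length(probeGene)
  nUnmapped <- round(config@unmappableFraction * nMapped /
                       max(1 - config@unmappableFraction, 1e-9))
  probeGene <- c(probeGene, rep(NA_character_, nUnmapped))
  nProbes <- length(probeGene)
  probes <- sprintf("P%06d", seq_len(nProbes))
  mapping <- data.frame(probe_id = probes, gene_id = probeGene,
                        stringsAsFactors = FALSE)

  ## planted truth
  if (is.null(truth)) {
    nDE <- floor(config@deFraction * config@nGenes)
    de <- if (nDE > 0) sample(genes, nDE) else character()
    up <- de[seq_len(ceiling(nDE / 2))]
    down <- setdiff(de, up)
    truth <- new("SyntheticTruth", deGenesUp = up, deGenesDown = down)
  }
  effect <- setNames(numeric(config@nGenes), genes)
  effect[truth@deGenesUp] <- config@deLog2FC
  effect[truth@deGenesDown] <- -config@deLog2FC

  ## background probes: unmappable ones plus enough mapped probes of
  ## non-planted genes to reach backgroundFraction of all probes
  isDEprobe <- !is.na(probeGene) & probeGene %in% deGenes(truth)
  nBackground <- round(config@backgroundFraction * nProbes)
  bg <- which(is.na(probeGene))
  pool <- which(!is.na(probeGene) & !isDEprobe)
  extra <- max(0L, nBackground - length(bg))
  if (extra > 0L) bg <- c(bg, sample(pool, min(extra, length(pool))))
  isBackground <- seq_len(nProbes) %in% bg

  n <- config@nTumor + config@nNormal
  samples <- c(sprintf("T%02d", seq_len(config@nTumor)),
               sprintf("N%02d", seq_len(config@nNormal)))
  groups <- setNames(rep(c("tumor", "normal"),
                         c(config@nTumor, config@nNormal)), samples)

  baseline <- rnorm(nProbes, config@baselineLog2Mean, config@baselineLog2Sd)
  baseline[isBackground] <- baseline[isBackground] - 3
  probeEffect <- ifelse(is.na(probeGene), 0, effect[probeGene])
  isTumor <- groups == "tumor"
  log2mat <- matrix(baseline, nProbes, n) +
    outer(probeEffect, as.numeric(isTumor)) +
    matrix(rnorm(nProbes * n, 0, config@noiseSd), nProbes, n)

  out <- character()
  if (config@nOutlierArrays > 0L) {
    out <- sample(samples, config@nOutlierArrays)
    log2mat[, samples %in% out] <- log2mat[, samples %in% out] +
      config@outlierShift
  }

  pCall <- ifelse(isBackground, config@detectProbBackground,
                  config@detectProbExpressed)
  calls <- matrix(rbinom(nProbes * n, 1L, rep(pCall, n)) == 1L, nProbes, n)

  dimnames(log2mat) <- dimnames(calls) <- list(probes, samples)
  em <- ExpressionMatrix(2^log2mat, calls, groups)
  metadata(em)$simSeed <- config@seed

  truth@outlierArrays <- out
  list(expression = em, mapping = mapping, truth = truth)
}

#' Simulate a scale-free protein interaction network with a planted module
#'
#' Generates a preferential-attachment (Barabasi-Albert) graph, then rewires
#' `plantedModuleSize` randomly chosen vertices into a connected subgraph (a
#' random spanning tree plus extra within-module edges) and labels those
#' vertices with planted differentially expressed genes; remaining vertices
#' get other gene identifiers from the expression universe.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class] from [simulateExpression()].
#' @return list with `graph` (a [WeightedGraph-class] with zero weights) and
#'   the updated `truth` carrying the planted module members.
#' @export
simulatePPI <- function(config, truth) {
  stopifnot(is(config, "SimConfig"), is(truth, "SyntheticTruth"))
  if (config@plantedModuleSize > config@ppiNodes)
    stop("planted module size exceeds the node count")
  de <- deGenes(truth)
  if (config@plantedModuleSize > 0 && length(de) < config@plantedModuleSize)
    stop("not enough planted DE genes to fill the module")
  set.seed(.streamSeed(config, 1L))

  g <- igraph::sample_pa(config@ppiNodes, m = config@ppiEdgesPerNode,
                         directed = FALSE)
  genes <- sprintf("G%05d", seq_len(config@nGenes))
  nodeLabels <- character(config@ppiNodes)
  moduleGenes <- character()
  if (config@plantedModuleSize > 0) {
    moduleIdx <- sample(config@ppiNodes, config@plantedModuleSize)
    moduleGenes <- sample(de, config@plantedModuleSize)
    nodeLabels[moduleIdx] <- moduleGenes
    ## rewire the module into a connected subgraph: random spanning tree
    ## plus sparse extra edges
    newEdges <- integer()
    if (length(moduleIdx) > 1) {
      for (i in 2:length(moduleIdx))
        newEdges <- c(newEdges, moduleIdx[i],
                      moduleIdx[sample.int(i - 1L, 1L)])
      pairs <- utils::combn(moduleIdx, 2)
      keep <- runif(ncol(pairs)) < 0.3
      newEdges <- c(newEdges, as.integer(pairs[, keep]))
    }
    if (length(newEdges)) g <- igraph::add_edges(g, newEdges)
  } else {
    moduleIdx <- integer()
  }
  nodeLabels[nodeLabels == ""] <-
    sample(setdiff(genes, moduleGenes), config@ppiNodes - length(moduleIdx))
  igraph::V(g)$name <- nodeLabels
  g <- igraph::simplify(g)

  truth@plantedModule <- moduleGenes
  list(graph = WeightedGraph(g), truth = truth)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Background sets are uniform draws from the gene universe. Designated
#' enriched sets (and the fixed secretory terms, carrying the GO identifiers
#' for serotonin metabolism, substance P signaling and secretion) sample
#' planted differentially expressed genes at `geneSetDEOdds`-fold odds.
#' Sets smaller than any downstream minimum-size filter are emitted as-is;
#' filtering is the enrichment stage's job.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class].
#' @return list with `genesets` (a [GeneSetList-class]) and updated `truth`.
#' @export
simulateGeneSets <- function(config, truth) {
  stopifnot(is(config, "SimConfig"), is(truth, "SyntheticTruth"))
  set.seed(.streamSeed(config, 2L))
  genes <- sprintf("G%05d", seq_len(config@nGenes))
  de <- deGenes(truth)
  odds <- ifelse(genes %in% de, config@geneSetDEOdds, 1)

  secretoryIds <- c("GO:0042428", "GO:0042427", "GO:0007210", "GO:0004993",
                    "GO:0071861", "GO:0007217", "GO:0007218", "GO:0030141")
  nBackground <- max(0L, config@nGeneSets - config@nEnrichedSets)
  ids <- c(sprintf("SET:%04d", seq_len(nBackground)),
           sprintf("ENR:%04d", seq_len(config@nEnrichedSets)),
           secretoryIds)
  enriched <- ids[grepl("^ENR:", ids)]
  oversampled <- c(enriched, secretoryIds)

  sizes <- sample(config@geneSetSizeRange[1]:config@geneSetSizeRange[2],
                  length(ids), replace = TRUE)
  sets <- lapply(seq_along(ids), function(i) {
    if (ids[i] %in% oversampled && length(de) > 0)
      sample(genes, sizes[i], prob = odds)
    else
      sample(genes, sizes[i])
  })
  names(sets) <- ids

  ns <- c(rep(c("BP", "CC", "MF", "pathway"),
              length.out = nBackground + length(enriched)),
          rep("secretory", length(secretoryIds)))
  gsl <- geneSetList(sets, namespace = ns)
  truth@enrichedSets <- oversampled
  list(genesets = gsl, truth = truth)
}

#' Simulate a qPCR cycle-threshold table
#'
#' Target CT values follow `CT = CT_base - log2(relative expression) +
#' N(0, qpcrSigma)`, with the housekeeping gene constant in expectation
#' across groups, so the delta-delta-CT method recovers the planted fold
#' changes exactly at `qpcrSigma = 0`.
#'
#' @param config a [SimConfig-class].
#' @param truth the [SyntheticTruth-class]; target genes are drawn from its
#'   planted DE genes (fold change `2^deLog2FC` up, `2^-deLog2FC` down).
#' @return list with `qpcr` (a [QPCRTable-class]) and updated `truth` whose
#'   `qpcrTrueFC` records the planted linear fold changes.
#' @export
simulateQPCR <- function(config, truth) {
  stopifnot(is(config, "SimConfig"), is(truth, "SyntheticTruth"))
  if (!nzchar(config@qpcrHkGene)) stop("a housekeeping gene is required")
  set.seed(.streamSeed(config, 3L))

  de <- deGenes(truth)
  nTargets <- min(config@nQpcrGenes, length(de))
  if (nTargets == 0L) stop("no planted DE genes available as qPCR targets")
  targets <- sample(de, nTargets)
  fc <- ifelse(targets %in% truth@deGenesUp,
               2^config@deLog2FC, 2^-config@deLog2FC)
  names(fc) <- targets

  samples <- c(sprintf("Q_T%02d", seq_len(config@qpcrTumor)),
               sprintf("Q_N%02d", seq_len(config@qpcrNormal)))
  groups <- rep(c("tumor", "normal"), c(config@qpcrTumor, config@qpcrNormal))
  isTumor <- groups == "tumor"
  n <- length(samples)

  ctBase <- runif(nTargets, 24, 30)
  ct <- matrix(0, n, nTargets + 1L,
               dimnames = list(samples, c(config@qpcrHkGene, targets)))
  ct[, 1] <- 20 + rnorm(n, 0, config@qpcrSigma)
  for (j in seq_len(nTargets)) {
    expr <- ifelse(isTumor, log2(fc[j]), 0)
    ct[, j + 1L] <- ctBase[j] - expr + rnorm(n, 0, config@qpcrSigma)
  }

  truth@qpcrTrueFC <- fc
  list(qpcr = QPCRTable(ct, groups, config@qpcrHkGene), truth = truth)
}

#' Simulate every input of the pipeline at once
#'
#' Convenience wrapper chaining [simulateExpression()], [simulatePPI()],
#' [simulateGeneSets()] and [simulateQPCR()] on independent RNG streams.
#'
#' @param config a [SimConfig-class].
#' @return list with `expression`, `mapping`, `graph`, `genesets`, `qpcr`
#'   and the fully populated `truth`.
#' @export
simulateStudy <- function(config) {
  ex <- simulateExpression(config)
  pp <- simulatePPI(config, ex$truth)
  gs <- simulateGeneSets(config, pp$truth)
  qp <- simulateQPCR(config, gs$truth)
  list(expression = ex$expression, mapping = ex$mapping,
       graph = pp$graph, genesets = gs$genesets, qpcr = qp$qpcr,
       truth = qp$truth)
}
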