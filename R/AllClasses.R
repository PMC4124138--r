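#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Holds every parameter of the synthetic-data generator. Defaults emulate
#' the design of a small two-group microarray study of small intestinal
#' neuroendocrine tumors: 9 tumor vs 3 normal arrays, log2-scale intensities
#' around 7 with unit spread, 5% of genes differentially expressed at a
#' symmetric log2 fold change of 2, and a scale-free interaction network
#' carrying a planted connected module of differentially expressed genes.
#'
#' @slot nGenes number of genes in the simulated universe.
#' @slot probesPerGene named numeric vector of sampling probabilities over
#'   per-gene probe counts (names are the counts).
#' @slot unmappableFraction fraction of emitted probes with no gene mapping.
#' @slot nTumor,nNormal group sizes.
#' @slot baselineLog2Mean,baselineLog2Sd per-probe baseline distribution on
#'   the log2 scale.
#' @slot deFraction fraction of genes planted as differentially expressed.
#' @slot deLog2FC magnitude of the planted log2 fold change (split evenly
#'   between up- and down-regulation).
#' @slot noiseSd per-measurement log2-scale noise standard deviation.
#' @slot detectProbExpressed,detectProbBackground Bernoulli present-call
#'   probabilities for expressed and background probes.
#' @slot backgroundFraction fraction of probes simulated at background level.
#' @slot nOutlierArrays number of whole-array outliers.
#' @slot outlierShift log2-scale shift applied to outlier arrays.
#' @slot ppiNodes,ppiEdgesPerNode size and preferential-attachment density of
#'   the simulated interaction network.
#' @slot plantedModuleSize size of the planted connected module of
#'   differentially expressed genes.
#' @slot nGeneSets,geneSetSizeRange,nEnrichedSets,geneSetDEOdds gene-set
#'   collection parameters; enriched sets oversample planted genes at the
#'   stated odds.
#' @slot nQpcrGenes,qpcrHkGene,qpcrSigma,qpcrTumor,qpcrNormal qPCR table
#'   parameters (target gene count, housekeeping gene id, CT noise SD and
#'   group sizes).
#' @slot seed master RNG seed; each artifact uses a stream derived from it.
#' @export
setClass("SimConfig",
  slots = c(
    nGenes = "integer", probesPerGene = "numeric",
    unmappableFraction = "numeric",
    nTumor = "integer", nNormal = "integer",
    baselineLog2Mean = "numeric", baselineLog2Sd = "numeric",
    deFraction = "numeric", deLog2FC = "numeric", noiseSd = "numeric",
    detectProbExpressed = "numeric", detectProbBackground = "numeric",
    backgroundFraction = "numeric",
    nOutlierArrays = "integer", outlierShift = "numeric",
    ppiNodes = "integer", ppiEdgesPerNode = "integer",
    plantedModuleSize = "integer",
    nGeneSets = "integer", geneSetSizeRange = "integer",
    nEnrichedSets = "integer", geneSetDEOdds = "numeric",
    nQpcrGenes = "integer", qpcrHkGene = "character", qpcrSigma = "numeric",
    qpcrTumor = "integer", qpcrNormal = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(object@detectProbExpressed, object@detectProbBackground,
             object@unmappableFraction, object@backgroundFraction,
             object@deFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities and fractions must lie in [0, 1]")
  counts <- c(object@nGenes, object@nTumor, object@nNormal,
              object@nOutlierArrays, object@ppiNodes, object@ppiEdgesPerNode,
              object@plantedModuleSize, object@nGeneSets, object@nQpcrGenes,
              object@qpcrTumor, object@qpcrNormal)
  if (any(counts < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (object@deFraction > 0 && object@deFraction * object@nGenes < 1)
    msg <- c(msg, "deFraction * nGenes must be >= 1 when DE is requested")
  if (is.null(names(object@probesPerGene)) ||
      any(is.na(as.integer(names(object@probesPerGene)))))
    msg <- c(msg, "probesPerGene must be named by integer probe counts")
  if (abs(sum(object@probesPerGene) - 1) > 1e-8)
    msg <- c(msg, "probesPerGene probabilities must sum to 1")
  if (object@plantedModuleSize > object@ppiNodes)
    msg <- c(msg, "plantedModuleSize cannot exceed ppiNodes")
  if (length(object@geneSetSizeRange) != 2L ||
      object@geneSetSizeRange[1] > object@geneSetSizeRange[2])
    msg <- c(msg, "geneSetSizeRange must be an increasing pair")
  if (object@geneSetSizeRange[2] > object@nGenes)
    msg <- c(msg, "gene set sizes cannot exceed the gene universe")
  if (object@noiseSd < 0 || object@baselineLog2Sd < 0 || object@qpcrSigma < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nGenes,probesPerGene,unmappableFraction,nTumor,nNormal,baselineLog2Mean,baselineLog2Sd,deFraction,deLog2FC,noiseSd,detectProbExpressed,detectProbBackground,backgroundFraction,nOutlierArrays,outlierShift,ppiNodes,ppiEdgesPerNode,plantedModuleSize,nGeneSets,geneSetSizeRange,nEnrichedSets,geneSetDEOdds,nQpcrGenes,qpcrHkGene,qpcrSigma,qpcrTumor,qpcrNormal,seed
#'   see the [SimConfig-class] slot documentation.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 200L, ppiNodes = 60L, seed = 7L)
#' @export
simConfig <- function(nGenes = 2000L,
                      probesPerGene = c(`1` = 0.5, `2` = 0.3, `3` = 0.2),
                      unmappableFraction = 0.05,
                      nTumor = 9L, nNormal = 3L,
                      baselineLog2Mean = 7, baselineLog2Sd = 1,
                      deFraction = 0.05, deLog2FC = 2, noiseSd = 0.5,
                      detectProbExpressed = 0.9, detectProbBackground = 0.3,
                      backgroundFraction = 0.3,
                      nOutlierArrays = 0L, outlierShift = 2,
                      ppiNodes = 300L, ppiEdgesPerNode = 3L,
                      plantedModuleSize = 20L,
                      nGeneSets = 50L, geneSetSizeRange = c(10L, 50L),
                      nEnrichedSets = 5L, geneSetDEOdds = 10,
                      nQpcrGenes = 8L, qpcrHkGene = "ALG9", qpcrSigma = 0.25,
                      qpcrTumor = 13L, qpcrNormal = 8L,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes), probesPerGene = probesPerGene,
      unmappableFraction = unmappableFraction,
      nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
      baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
      deFraction = deFraction, deLog2FC = deLog2FC, noiseSd = noiseSd,
      detectProbExpressed = detectProbExpressed,
      detectProbBackground = detectProbBackground,
      backgroundFraction = backgroundFraction,
      nOutlierArrays = as.integer(nOutlierArrays), outlierShift = outlierShift,
      ppiNodes = as.integer(ppiNodes),
      ppiEdgesPerNode = as.integer(ppiEdgesPerNode),
      plantedModuleSize = as.integer(plantedModuleSize),
      nGeneSets = as.integer(nGeneSets),
      geneSetSizeRange = as.integer(geneSetSizeRange),
      nEnrichedSets = as.integer(nEnrichedSets), geneSetDEOdds = geneSetDEOdds,
      nQpcrGenes = as.integer(nQpcrGenes), qpcrHkGene = qpcrHkGene,
      qpcrSigma = qpcrSigma,
      qpcrTumor = as.integer(qpcrTumor), qpcrNormal = as.integer(qpcrNormal),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic study
#'
#' Records what was planted by the generator so recovery can be measured:
#' up/down differentially expressed genes, whole-array outliers, the planted
#' network module, the oversampled ("enriched") gene sets, and the true qPCR
#' fold changes.
#'
#' @slot deGenesUp,deGenesDown,outlierArrays,plantedModule,enrichedSets
#'   character vectors of identifiers.
#' @slot qpcrTrueFC named numeric vector of linear fold changes.
#' @export
setClass("SyntheticTruth",
  slots = c(deGenesUp = "character", deGenesDown = "character",
            outlierArrays = "character", plantedModule = "character",
            enrichedSets = "character", qpcrTrueFC = "numeric"),
  prototype = prototype(deGenesUp = character(), deGenesDown = character(),
                        outlierArrays = character(),
                        plantedModule = character(),
                        enrichedSets = character(), qpcrTrueFC = numeric())
)

setValidity("SyntheticTruth", function(object) {
  if (length(intersect(object@deGenesUp, object@deGenesDown)))
    return("deGenesUp and deGenesDown must be disjoint")
  TRUE
})

#' @describeIn SyntheticTruth-class planted up-regulated genes
#' @param x,object a `SyntheticTruth`
#' @export
deGenesUp <- function(x) x@deGenesUp
#' @describeIn SyntheticTruth-class planted down-regulated genes
#' @export
deGenesDown <- function(x) x@deGenesDown
#' @describeIn SyntheticTruth-class all planted DE genes
#' @export
deGenes <- function(x) c(x@deGenesUp, x@deGenesDown)
#' @describeIn SyntheticTruth-class planted outlier arrays
#' @export
outlierArrays <- function(x) x@outlierArrays
#' @describeIn SyntheticTruth-class planted network module members
#' @export
plantedModule <- function(x) x@plantedModule
#' @describeIn SyntheticTruth-class identifiers of the oversampled gene sets
#' @export
enrichedSets <- function(x) x@enrichedSets
#' @describeIn SyntheticTruth-class planted qPCR fold changes
#' @export
qpcrTrueFC <- function(x) x@qpcrTrueFC

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:",
      length(object@deGenesUp), "up /", length(object@deGenesDown),
      "down DE genes;", length(object@outlierArrays), "outlier arrays;",
      "module of", length(object@plantedModule), "nodes;",
      length(object@enrichedSets), "enriched sets;",
      length(object@qpcrTrueFC), "qPCR genes\n")
})

## ---------------------------------------------------------------------------
## ExpressionMatrix / GeneMatrix
## ---------------------------------------------------------------------------

#' Probe-level expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays, `exprs`
#' (non-negative intensities; linear scale on input, log2 scale after
#' [quantileNormalize()]) and `calls` (present/absent detection flags), and a
#' `group` column ("tumor"/"normal") in `colData`.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("exprs", "calls") %in% an))
    return("assays 'exprs' and 'calls' are required")
  if (any(assay(object, "exprs") < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    grp <- colData(object)$group
    if (anyNA(grp)) msg <- c(msg, "every sample needs a group")
    if (!all(as.character(grp) %in% c("tumor", "normal")))
      msg <- c(msg, "groups must be 'tumor' or 'normal'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param intensities probe x sample numeric matrix (non-negative).
#' @param calls probe x sample logical (or 0/1) matrix of present calls.
#' @param groups character/factor of length `ncol(intensities)` with values
#'   "tumor"/"normal", named by sample or in column order.
#' @return An [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(intensities, calls, groups) {
  if (!identical(dim(intensities), dim(calls)))
    stop("intensity and call matrices must have identical dimensions")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate probe identifiers")
  storage.mode(calls) <- "logical"
  grp <- factor(as.character(groups), levels = c("normal", "tumor"))
  se <- SummarizedExperiment(
    assays = list(exprs = intensities, calls = calls),
    colData = DataFrame(group = grp, row.names = colnames(intensities)))
  new("ExpressionMatrix", se)
}

#' Gene-level log2 expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `log2` of
#' finite gene x sample values and a `group` column in `colData`.
#'
#' @export
setClass("GeneMatrix", contains = "SummarizedExperiment")

setValidity("GeneMatrix", function(object) {
  msg <- character()
  if (!"log2" %in% names(assays(object)))
    return("assay 'log2' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be unique")
  if (any(!is.finite(assay(object, "log2"))))
    msg <- c(msg, "log2 values must be finite")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneMatrix
#'
#' @param log2values gene x sample numeric matrix on the log2 scale.
#' @param groups sample groups ("tumor"/"normal").
#' @return A [GeneMatrix-class].
#' @export
GeneMatrix <- function(log2values, groups) {
  grp <- factor(as.character(groups), levels = c("normal", "tumor"))
  se <- SummarizedExperiment(
    assays = list(log2 = log2values),
    colData = DataFrame(group = grp, row.names = colnames(log2values)))
  new("GeneMatrix", se)
}

#' Sample group accessor
#'
#' @param x an [ExpressionMatrix-class], [GeneMatrix-class] or
#'   [QPCRTable-class].
#' @return Factor of "tumor"/"normal" labels named by sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
})

#' Intensity / log2-value accessors
#'
#' @param x the container.
#' @return `intensities()` returns the `exprs` assay, `detectionCalls()` the
#'   logical call matrix, `log2Values()` the gene-level log2 matrix.
#' @export
intensities <- function(x) assay(x, "exprs")

#' @rdname intensities
#' @export
detectionCalls <- function(x) assay(x, "calls")

#' @rdname intensities
#' @export
log2Values <- function(x) assay(x, "log2")

## ---------------------------------------------------------------------------
## QCReport
## ---------------------------------------------------------------------------

#' Array quality-control report
#'
#' @slot nProbesIn,nProbesRetained probe counts before/after detection
#'   filtering (NA when the filter was not run).
#' @slot ksStat per-array Kolmogorov-Smirnov statistic D against the pooled
#'   intensity distribution.
#' @slot outliers arrays flagged by the Tukey upper fence on D.
#' @slot threshold the fence Q3 + 1.5 IQR actually used.
#' @export
setClass("QCReport",
  slots = c(nProbesIn = "integer", nProbesRetained = "integer",
            ksStat = "numeric", outliers = "character",
            threshold = "numeric"),
  prototype = prototype(nProbesIn = NA_integer_,
                        nProbesRetained = NA_integer_))

setValidity("QCReport", function(object) {
  msg <- character()
  if (any(object@ksStat < 0 | object@ksStat > 1))
    msg <- c(msg, "KS statistics must lie in [0, 1]")
  if (!all(object@outliers %in% names(object@ksStat)))
    msg <- c(msg, "outliers must be a subset of the scored arrays")
  if (length(msg)) msg else TRUE
})

#' @describeIn QCReport-class per-array KS statistics
#' @param x,object a `QCReport`
#' @export
ksStat <- function(x) x@ksStat
#' @describeIn QCReport-class flagged arrays
#' @export
qcOutliers <- function(x) x@outliers

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", length(object@ksStat), "arrays, ",
      length(object@outliers), "outlier(s); fence =",
      format(object@threshold, digits = 4), "\n")
  if (!is.na(object@nProbesIn))
    cat("  probes:", object@nProbesIn, "->", object@nProbesRetained,
        "after detection filtering\n")
})

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' A collection of gene sets
#'
#' @slot sets named list of character vectors (term id -> member genes).
#' @slot namespace named character: one of "BP", "CC", "MF", "pathway",
#'   "secretory" per term.
#' @slot labels named character of human-readable term names.
#' @export
setClass("GeneSetList",
  slots = c(sets = "list", namespace = "character", labels = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (is.null(ids) || anyDuplicated(ids))
    return("sets must be uniquely named by term id")
  if (any(lengths(object@sets) == 0))
    msg <- c(msg, "gene sets must be non-empty")
  if (!setequal(names(object@namespace), ids))
    msg <- c(msg, "namespace must be named by the same term ids")
  if (length(msg)) msg else TRUE
})

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors.
#' @param namespace per-set namespace tags; recycled if length 1.
#' @param labels per-set labels; defaults to the ids.
#' @return A [GeneSetList-class].
#' @export
geneSetList <- function(sets, namespace = "pathway", labels = NULL) {
  ids <- names(sets)
  if (length(namespace) == 1L) namespace <- rep(namespace, length(sets))
  names(namespace) <- ids
  if (is.null(labels)) labels <- ids
  if (is.null(names(labels))) names(labels) <- ids
  new("GeneSetList", sets = sets, namespace = namespace,
      labels = labels)
}

#' @describeIn GeneSetList-class the named list of sets
#' @param x,object a collection
#' @export
geneSets <- function(x) x@sets
#' @describeIn GeneSetList-class per-term namespaces
#' @export
setNamespace <- function(x) x@namespace

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList:", length(object@sets), "sets;",
      "sizes", min(lengths(object@sets)), "-", max(lengths(object@sets)),
      "\n  namespaces:",
      paste(names(table(object@namespace)), table(object@namespace),
            sep = ":", collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## WeightedGraph / Subnetwork / CommunityPartition
## ---------------------------------------------------------------------------

#' Node-weighted interaction graph
#'
#' Wraps an undirected [igraph::igraph] whose vertices carry gene symbols
#' (`name`), non-negative weights (`weight`, typically -log10 of a
#' differential expression p-value) and a logical `seed` flag marking
#' consensus differentially expressed genes.
#'
#' @slot graph the underlying igraph object.
#' @export
setClass("WeightedGraph", slots = c(graph = "ANY"))

setValidity("WeightedGraph", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (is.null(igraph::V(g)$name)) msg <- c(msg, "vertices must be named")
  w <- igraph::V(g)$weight
  if (is.null(w) || any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "vertex weights must be finite and >= 0")
  if (is.null(igraph::V(g)$seed))
    msg <- c(msg, "vertices need a logical 'seed' flag")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedGraph
#'
#' @param graph an undirected igraph with named vertices.
#' @param weights named numeric of node weights (defaults to 0).
#' @param seeds character vector of seed node names.
#' @return A [WeightedGraph-class].
#' @export
WeightedGraph <- function(graph, weights = NULL, seeds = character()) {
  graph <- igraph::simplify(graph, remove.multiple = TRUE,
                            remove.loops = TRUE)
  nm <- igraph::V(graph)$name
  w <- setNames(numeric(length(nm)), nm)
  if (!is.null(weights)) {
    common <- intersect(names(weights), nm)
    w[common] <- weights[common]
  }
  igraph::V(graph)$weight <- unname(w)
  igraph::V(graph)$seed <- nm %in% seeds
  new("WeightedGraph", graph = graph)
}

#' @describeIn WeightedGraph-class named node weights
#' @param x,object a `WeightedGraph`
#' @export
nodeWeights <- function(x) {
  g <- x@graph
  setNames(igraph::V(g)$weight, igraph::V(g)$name)
}
#' @describeIn WeightedGraph-class names of seed nodes
#' @export
seedNodes <- function(x) {
  g <- x@graph
  igraph::V(g)$name[igraph::V(g)$seed]
}
#' @describeIn WeightedGraph-class the underlying igraph
#' @export
asIgraph <- function(x) x@graph

setMethod("show", "WeightedGraph", function(object) {
  g <- object@graph
  cat("WeightedGraph:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges;", sum(igraph::V(g)$seed), "seed node(s)\n")
})

#' Extracted subnetwork of seeds and linkers
#'
#' @slot graph igraph holding the union of selected paths (or an induced
#'   subgraph for annotation subnetworks).
#' @slot seeds,linkers node name vectors; linkers are non-seed nodes lying on
#'   a selected maximum-weight shortest path.
#' @slot pathRecords per seed pair, a list with elements `path` (node
#'   sequence) and `W` (sum of node weights on the path).
#' @slot skippedPairs data.frame of seed pairs in different components.
#' @slot nodeInfo data.frame of per-node annotation (used by
#'   [secretorySubnetwork()]).
#' @export
setClass("Subnetwork",
  slots = c(graph = "ANY", seeds = "character", linkers = "character",
            pathRecords = "list", skippedPairs = "data.frame",
            nodeInfo = "data.frame"),
  prototype = prototype(pathRecords = list(),
                        skippedPairs = data.frame(u = character(),
                                                  v = character()),
                        nodeInfo = data.frame()))

setValidity("Subnetwork", function(object) {
  if (length(intersect(object@seeds, object@linkers)))
    return("linkers and seeds must be disjoint")
  TRUE
})

#' @describeIn Subnetwork-class linker node names
#' @param x,object a `Subnetwork`
#' @export
linkerNodes <- function(x) x@linkers
#' @describeIn Subnetwork-class per-pair path records
#' @export
pathRecords <- function(x) x@pathRecords
#' @describeIn Subnetwork-class node names in the subnetwork
#' @export
subnetworkNodes <- function(x) {
  if (igraph::vcount(x@graph) == 0) character() else igraph::V(x@graph)$name
}

setMethod("show", "Subnetwork", function(object) {
  cat("Subnetwork:", igraph::vcount(object@graph), "nodes (",
      length(object@seeds), "seeds,", length(object@linkers), "linkers ),",
      igraph::ecount(object@graph), "edges;",
      length(object@pathRecords), "path record(s)\n")
  if (nrow(object@skippedPairs))
    cat("  ", nrow(object@skippedPairs),
        "seed pair(s) skipped (different components)\n")
})

#' Community partition of a graph
#'
#' @slot membership named integer vector, node -> community id (1-based).
#' @slot Q the modularity of the partition.
#' @export
setClass("CommunityPartition",
  slots = c(membership = "integer", Q = "numeric"))

setValidity("CommunityPartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)) || anyNA(object@membership))
    msg <- c(msg, "every node must be assigned exactly one community")
  if (object@Q < -1 - 1e-12 || object@Q > 1 + 1e-12)
    msg <- c(msg, "modularity must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityPartition-class node -> community assignment
#' @param x,object a `CommunityPartition`
#' @export
communityMembership <- function(x) x@membership
#' @describeIn CommunityPartition-class modularity Q of the partition
#' @export
modularityScore <- function(x) x@Q
#' @describeIn CommunityPartition-class communities as a list of node sets
#' @export
communityList <- function(x) {
  split(names(x@membership), x@membership)
}

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", length(unique(object@membership)),
      "communities over", length(object@membership), "nodes; Q =",
      format(object@Q, digits = 4), "\n")
})

## ---------------------------------------------------------------------------
## MgsaResult
## ---------------------------------------------------------------------------

#' Model-based gene-set activation result
#'
#' Posterior activation probabilities of a Bayesian on/off set-activation
#' model explaining the observed differentially expressed gene labels with
#' false-positive rate `alpha` and false-negative rate `beta`.
#'
#' @slot posterior named numeric in \[0, 1\], one entry per set.
#' @slot alpha,beta,prior model parameters.
#' @slot method "exact" (full enumeration) or "mcmc".
#' @slot nSweeps,seed sampler settings (NA for exact).
#' @export
setClass("MgsaResult",
  slots = c(posterior = "numeric", alpha = "numeric", beta = "numeric",
            prior = "numeric", method = "character", nSweeps = "numeric",
            seed = "numeric"))

setValidity("MgsaResult", function(object) {
  if (length(object@posterior) &&
      any(object@posterior < -1e-12 | object@posterior > 1 + 1e-12))
    return("posteriors must lie in [0, 1]")
  TRUE
})

#' @describeIn MgsaResult-class named posterior activation probabilities
#' @param x,object an `MgsaResult`
#' @export
setPosterior <- function(x) x@posterior

setMethod("show", "MgsaResult", function(object) {
  cat("MgsaResult (", object@method, "): ", length(object@posterior),
      " sets; alpha=", object@alpha, " beta=", object@beta,
      " prior=", object@prior, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## QPCRTable
## ---------------------------------------------------------------------------

#' qPCR cycle-threshold table
#'
#' @slot ct sample x gene matrix of CT values (housekeeping gene included as
#'   a column).
#' @slot group factor of "tumor"/"normal" named by sample.
#' @slot housekeeping the housekeeping gene id used for normalization.
#' @export
setClass("QPCRTable",
  slots = c(ct = "matrix", group = "factor", housekeeping = "character"))

setValidity("QPCRTable", function(object) {
  msg <- character()
  if (!object@housekeeping %in% colnames(object@ct))
    msg <- c(msg, sprintf("housekeeping gene '%s' missing from the CT table",
                          object@housekeeping))
  if (any(!is.finite(object@ct))) msg <- c(msg, "CT values must be finite")
  if (!identical(names(object@group), rownames(object@ct)))
    msg <- c(msg, "group must be named by the CT table samples")
  if (length(msg)) msg else TRUE
})

#' Construct a QPCRTable
#'
#' @param ct sample x gene CT matrix.
#' @param groups "tumor"/"normal" per sample.
#' @param housekeeping housekeeping gene column name (default "ALG9").
#' @return A [QPCRTable-class].
#' @export
QPCRTable <- function(ct, groups, housekeeping = "ALG9") {
  grp <- factor(as.character(groups), levels = c("normal", "tumor"))
  names(grp) <- rownames(ct)
  new("QPCRTable", ct = ct, group = grp, housekeeping = housekeeping)
}

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "QPCRTable", function(x) x@group)

#' @describeIn QPCRTable-class the CT matrix
#' @param x,object a `QPCRTable`
#' @export
ctValues <- function(x) x@ct
#' @describeIn QPCRTable-class the housekeeping gene id
#' @export
housekeepingGene <- function(x) x@housekeeping

setMethod("show", "QPCRTable", function(object) {
  cat("QPCRTable:", nrow(object@ct), "samples x", ncol(object@ct),
      "genes (housekeeping:", object@housekeeping, ");",
      sum(object@group == "tumor"), "tumor /",
      sum(object@group == "normal"), "normal\n")
})
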