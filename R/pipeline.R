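## End-to-end orchestration on simulated inputs: QC -> consensus DE ->
## enrichment -> network extraction -> communities (-> co-analysis, qPCR),
## with a manifest recording inputs, parameters, seed and per-stage counts.

.configHash <- function(config) {
  ## stable fingerprint of the configuration without extra dependencies
  txt <- paste(deparse(lapply(slotNames(config), function(s)
    slot(config, s))), collapse = "")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

## flagged arrays are only removed while both groups keep >= 2 members; a
## minority group under strong asymmetric differential expression can drift
## from the pooled distribution, and dropping it would break the design
.dropOutlierArrays <- function(samples, groups, flagged) {
  keep <- setdiff(samples, flagged)
  for (g in c("tumor", "normal")) {
    if (sum(groups[keep] == g) < 2L) {
      restore <- intersect(flagged, samples[groups == g])
      if (length(restore))
        warning("keeping flagged array(s) ", paste(restore, collapse = ", "),
                " to preserve >= 2 samples in the ", g, " group")
      keep <- union(keep, restore)
    }
  }
  samples[samples %in% keep]
}

#' QC and consensus DE for one expression study
#'
#' The standard per-study chain: detection filtering, KS outlier scoring on
#' the unnormalized intensities (flagged arrays are dropped only while both
#' groups keep at least 2 members), quantile normalization, probe
#' collapsing and the consensus differential expression call.
#'
#' @param expression an [ExpressionMatrix-class].
#' @param mapping probe-to-gene mapping data.frame.
#' @param de a [deConfig()].
#' @param minDetection detection-filter fraction.
#' @return list with `qc` ([QCReport-class]), `genes` ([GeneMatrix-class])
#'   and `de` (consensus data.frame).
#' @export
analyzeStudy <- function(expression, mapping, de = deConfig(),
                         minDetection = 0.5) {
  filt <- filterByDetection(expression, minDetection)
  qc <- ksOutlierDetection(filt)
  keep <- .dropOutlierArrays(colnames(filt), sampleGroups(filt),
                             qcOutliers(qc))
  norm <- quantileNormalize(filt[, keep])
  gm <- collapseProbesToGenes(norm, mapping)
  list(qc = qc, genes = gm, de = runDiffExpr(gm, de))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates every input from `config`, then runs the toggled stages in
#' order: detection filtering + quantile normalization + KS outlier
#' detection + probe collapsing (`qc`), consensus differential expression
#' (`de`), hypergeometric and model-based enrichment (`enrich`), node
#' weighting + seed/linker subnetwork extraction (`network`), greedy
#' modularity communities on the extracted subnetwork (`communities`), and
#' delta-delta-CT quantification with Mann-Whitney tests (`qpcr`). With
#' `coanalysisSeed` set, a second study with the same planted truth (new
#' noise and arrays) is simulated, analyzed, and compared (fold-change
#' correlation, shared DE genes, top-k Jaccard, enrichment overlap).
#'
#' The result bundle is deterministic given `config`; rerunning writes
#' byte-identical outputs.
#'
#' @param config a [SimConfig-class].
#' @param de a [deConfig()].
#' @param stages named logical vector toggling `qc`, `de`, `enrich`,
#'   `network`, `communities`, `qpcr` (later stages require earlier ones).
#' @param coanalysisSeed optional integer seed for a second same-truth study.
#' @param outDir optional directory; when given, tables and a
#'   `manifest.json` are written there, each file headed by the config hash
#'   and seed.
#' @param minDetection detection-filter fraction (default 0.5).
#' @param minSetSize enrichment minimum term size (default 10).
#' @param mgsaSweeps MCMC sweeps for the set-activation model.
#' @param topk top-k size for the co-analysis ranking overlap.
#' @return Invisibly, a list bundle with the per-stage objects (`qc`,
#'   `genes`, `de`, `enrichment`, `mgsa`, `network`, `subnetwork`,
#'   `communities`, `qpcr`, `coanalysis`, `truth`, `manifest`).
#' @examples
#' bundle <- runPipeline(simConfig(nGenes = 150L, ppiNodes = 60L,
#'                                 plantedModuleSize = 8L),
#'                       de = deConfig(nPermutations = 100L),
#'                       stages = c(qc = TRUE, de = TRUE, enrich = FALSE,
#'                                  network = FALSE, communities = FALSE,
#'                                  qpcr = FALSE))
#' bundle$manifest$counts
#' @export
runPipeline <- function(config,
                        de = deConfig(),
                        stages = c(qc = TRUE, de = TRUE, enrich = TRUE,
                                   network = TRUE, communities = TRUE,
                                   qpcr = TRUE),
                        coanalysisSeed = NULL,
                        outDir = NULL,
                        minDetection = 0.5,
                        minSetSize = 10L,
                        mgsaSweeps = 2e4,
                        topk = 100L) {
  stopifnot(is(config, "SimConfig"))
  defaults <- c(qc = TRUE, de = TRUE, enrich = TRUE, network = TRUE,
                communities = TRUE, qpcr = TRUE)
  defaults[names(stages)] <- stages
  stages <- defaults

  sim <- simulateStudy(config)
  truth <- sim$truth
  bundle <- list(truth = truth, mapping = sim$mapping)
  counts <- list(n_probes_in = nrow(sim$expression),
                 n_samples = ncol(sim$expression))
  skippedStages <- character()

  ## outlier detection runs on the filtered, unnormalized intensities:
  ## quantile normalization forces identical column distributions, so KS
  ## scores must be taken before it
  if (stages[["qc"]]) {
    filt <- filterByDetection(sim$expression, minDetection)
    bundle$qc <- ksOutlierDetection(filt)
    counts$n_probes_retained <- metadata(filt)$nProbesRetained
    counts$n_outlier_arrays <- length(qcOutliers(bundle$qc))
    keep <- .dropOutlierArrays(colnames(filt), sampleGroups(filt),
                               qcOutliers(bundle$qc))
    norm <- quantileNormalize(filt[, keep])
    bundle$genes <- collapseProbesToGenes(norm, sim$mapping)
    counts$n_genes <- nrow(bundle$genes)
  } else skippedStages <- c(skippedStages, "qc")

  if (stages[["de"]] && stages[["qc"]]) {
    bundle$de <- runDiffExpr(bundle$genes, de)
    counts$n_consensus_de <- sum(bundle$de$consensus)
    counts$n_up <- sum(bundle$de$consensus & bundle$de$direction == "up")
    counts$n_down <- sum(bundle$de$consensus & bundle$de$direction == "down")
  } else skippedStages <- c(skippedStages, "de")

  if (stages[["enrich"]] && !is.null(bundle$de)) {
    deGenesNow <- bundle$de$gene_id[bundle$de$consensus]
    universe <- bundle$de$gene_id
    if (length(deGenesNow)) {
      bundle$enrichment <- hypergeometricEnrichment(
        deGenesNow, universe, sim$genesets, minSize = minSetSize)
      bundle$mgsa <- mgsa(deGenesNow, universe, sim$genesets,
                          nSweeps = mgsaSweeps, seed = config@seed,
                          exactLimit = 12L)
      counts$n_enriched_terms <- sum(bundle$enrichment$p_adj <= de$alpha)
    }
  } else skippedStages <- c(skippedStages, "enrich")

  if (stages[["network"]] && !is.null(bundle$de)) {
    bundle$network <- assignNodeWeights(sim$graph, bundle$de)
    if (length(seedNodes(bundle$network)) >= 2L) {
      bundle$subnetwork <- extractSubnetwork(bundle$network)
      counts$n_subnetwork_nodes <- length(subnetworkNodes(bundle$subnetwork))
      counts$n_linkers <- length(linkerNodes(bundle$subnetwork))
    }
  } else skippedStages <- c(skippedStages, "network")

  if (stages[["communities"]] && !is.null(bundle$subnetwork) &&
      igraph::ecount(bundle$subnetwork@graph) > 0) {
    bundle$communities <- detectCommunities(bundle$subnetwork@graph)
    counts$n_communities <-
      length(unique(communityMembership(bundle$communities)))
    counts$modularity <- modularityScore(bundle$communities)
  } else skippedStages <- c(skippedStages, "communities")

  if (stages[["qpcr"]]) {
    targets <- setdiff(colnames(ctValues(sim$qpcr)),
                       housekeepingGene(sim$qpcr))
    bundle$qpcr <- lapply(setNames(targets, targets), function(gene) {
      fc <- ddctFoldChange(sim$qpcr, gene)
      c(list(gene = gene,
             mean_fc_tumor = fc$summary["tumor", "mean_fc"]),
        groupCompare(sim$qpcr, gene))
    })
    counts$n_qpcr_significant <- sum(vapply(bundle$qpcr,
                                            function(x) x$p_mw, 0) < 0.05)
  } else skippedStages <- c(skippedStages, "qpcr")

  if (!is.null(coanalysisSeed)) {
    cfg2 <- config
    cfg2@seed <- as.integer(coanalysisSeed)
    sim2 <- simulateExpression(cfg2, truth = truth)
    res2 <- analyzeStudy(sim2$expression, sim2$mapping, de = de,
                         minDetection = minDetection)
    k <- min(topk, nrow(bundle$de), nrow(res2$de))
    bundle$coanalysis <- list(
      de2 = res2$de,
      correlation = correlateFoldChanges(bundle$de, res2$de),
      shared = sharedDEGenes(bundle$de, res2$de),
      topk_jaccard = topkJaccard(bundle$de, res2$de, k = k))
    counts$coanalysis_r <- bundle$coanalysis$correlation$r
    counts$n_shared_de <- length(bundle$coanalysis$shared$shared)
  }

  manifest <- list(
    package = "consensusNET",
    version = as.character(utils::packageVersion("consensusNET")),
    seed = config@seed,
    config_hash = .configHash(config),
    de_config = unclass(de),
    stages_run = names(stages)[stages],
    stages_skipped = skippedStages,
    counts = counts)
  bundle$manifest <- manifest

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(config_hash = manifest$config_hash,
              seed = as.character(config@seed))
    if (!is.null(bundle$de))
      writeDEResult(bundle$de, file.path(outDir, "de_results.tsv"), meta)
    if (!is.null(bundle$enrichment))
      .writeTsv(bundle$enrichment, file.path(outDir, "enrichment.tsv"), meta)
    if (!is.null(bundle$subnetwork))
      writeEdgelist(bundle$subnetwork@graph,
                    file.path(outDir, "subnetwork_edges.tsv"), meta)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}
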