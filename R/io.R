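## Readers and writers for the pipeline's plain-text formats: wide TSV
## expression/call matrices, sample tables, probe mappings, edge lists, GMT
## gene sets, long-format CT tables and one-symbol-per-line gene lists.
## Writers prepend "#key=value" header comments (seed, config hash);
## readers skip them.

.writeTsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("#", names(meta), "=", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read an expression study
#'
#' `writeExpression()` writes `<prefix>_exprs.tsv`, `<prefix>_calls.tsv` and
#' `<prefix>_samples.tsv`; `readExpression()` reads them back into an
#' [ExpressionMatrix-class]. Dimension mismatches and duplicate probe ids
#' are rejected.
#'
#' @param m an [ExpressionMatrix-class].
#' @param prefix file path prefix.
#' @param meta named character vector written as `#key=value` header lines.
#' @return `readExpression()` returns an [ExpressionMatrix-class];
#'   `writeExpression()` the prefix, invisibly.
#' @export
writeExpression <- function(m, prefix, meta = character()) {
  stopifnot(is(m, "ExpressionMatrix"))
  ex <- data.frame(probe_id = rownames(m), intensities(m),
                   check.names = FALSE)
  ca <- data.frame(probe_id = rownames(m), detectionCalls(m) + 0L,
                   check.names = FALSE)
  sa <- data.frame(sample_id = colnames(m),
                   group = as.character(sampleGroups(m)))
  .writeTsv(ex, paste0(prefix, "_exprs.tsv"), meta)
  .writeTsv(ca, paste0(prefix, "_calls.tsv"), meta)
  .writeTsv(sa, paste0(prefix, "_samples.tsv"), meta)
  invisible(prefix)
}

#' @rdname writeExpression
#' @export
readExpression <- function(prefix) {
  ex <- .readTsv(paste0(prefix, "_exprs.tsv"))
  ca <- .readTsv(paste0(prefix, "_calls.tsv"))
  sa <- .readTsv(paste0(prefix, "_samples.tsv"))
  if (anyDuplicated(ex$probe_id)) stop("duplicate probe identifiers")
  probes <- ex$probe_id
  xm <- as.matrix(ex[, -1, drop = FALSE]); rownames(xm) <- probes
  cm <- as.matrix(ca[, -1, drop = FALSE]) == 1; rownames(cm) <- ca$probe_id
  if (!identical(dim(xm), dim(cm)) || !identical(rownames(xm), rownames(cm)))
    stop("intensity and call matrices disagree in dimensions or probes")
  groups <- setNames(sa$group, sa$sample_id)[colnames(xm)]
  if (anyNA(groups)) stop("samples missing from the sample table")
  ExpressionMatrix(xm, cm, groups)
}

#' Write / read a probe-to-gene mapping table
#'
#' @param mapping data.frame with `probe_id`, `gene_id` columns (NA or empty
#'   gene_id = unmappable).
#' @param path file path.
#' @param meta header metadata.
#' @return `readMapping()` returns the mapping data.frame.
#' @export
writeMapping <- function(mapping, path, meta = character()) {
  .writeTsv(mapping, path, meta)
  invisible(path)
}

#' @rdname writeMapping
#' @export
readMapping <- function(path) {
  mp <- .readTsv(path)
  mp$gene_id[!nzchar(mp$gene_id) | is.na(mp$gene_id)] <- NA_character_
  mp
}

#' Read / write an interaction edge list
#'
#' Tab-separated with 2 or 3 columns (`node_a`, `node_b`, optional source
#' tag). Self-loops are rejected with the offending line number; duplicate
#' edges are collapsed.
#'
#' @param path file path.
#' @return `readEdgelist()` returns an undirected igraph.
#' @export
readEdgelist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed edge line(s): ", paste(lineNo[bad], collapse = ", "))
  ## skip a header line if present
  if (identical(tolower(parts[[1]][1:2]), c("node_a", "node_b"))) {
    parts <- parts[-1]; lineNo <- lineNo[-1]
  }
  a <- vapply(parts, `[`, "", 1); b <- vapply(parts, `[`, "", 2)
  loops <- which(a == b)
  if (length(loops))
    stop("self-loop(s) at line(s): ", paste(lineNo[loops], collapse = ", "))
  igraph::simplify(
    igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE))
}

#' @rdname readEdgelist
#' @param g igraph or [WeightedGraph-class] to write.
#' @param meta header metadata.
#' @export
writeEdgelist <- function(g, path, meta = character()) {
  ig <- if (is(g, "WeightedGraph")) g@graph else g
  el <- igraph::as_edgelist(ig, names = TRUE)
  .writeTsv(data.frame(node_a = el[, 1], node_b = el[, 2]), path, meta)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One tab-separated line per set: id, description, member genes. Lines with
#' fewer than 3 fields are rejected with their line number. The description
#' field carries the namespace tag when it is one of BP/CC/MF/pathway/
#' secretory (otherwise the namespace defaults to "pathway").
#'
#' @param path file path.
#' @return `readGMT()` returns a [GeneSetList-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(keep[bad], collapse = ", "))
  ids <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  known <- c("BP", "CC", "MF", "pathway", "secretory")
  ns <- ifelse(desc %in% known, desc, "pathway")
  geneSetList(sets, namespace = ns, labels = setNames(desc, ids))
}

#' @rdname readGMT
#' @param gs a [GeneSetList-class] to write.
#' @param meta header metadata.
#' @export
writeGMT <- function(gs, path, meta = character()) {
  stopifnot(is(gs, "GeneSetList"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("#", names(meta), "=", meta), con)
  for (id in names(gs@sets))
    writeLines(paste(c(id, gs@namespace[[id]], gs@sets[[id]]),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read / write a long-format CT table
#'
#' Tab-separated columns `sample`, `group`, `gene`, `ct`.
#'
#' @param path file path.
#' @param housekeeping housekeeping gene id (default "ALG9").
#' @return `readCT()` returns a [QPCRTable-class].
#' @export
readCT <- function(path, housekeeping = "ALG9") {
  df <- .readTsv(path)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% colnames(df)))
    stop("CT table needs columns: ", paste(need, collapse = ", "))
  samples <- unique(df$sample)
  genes <- unique(df$gene)
  ct <- matrix(NA_real_, length(samples), length(genes),
               dimnames = list(samples, genes))
  ct[cbind(match(df$sample, samples), match(df$gene, genes))] <- df$ct
  groups <- df$group[match(samples, df$sample)]
  QPCRTable(ct, groups, housekeeping)
}

#' @rdname readCT
#' @param t a [QPCRTable-class] to write.
#' @param meta header metadata.
#' @export
writeCT <- function(t, path, meta = character()) {
  stopifnot(is(t, "QPCRTable"))
  ct <- ctValues(t)
  grp <- as.character(sampleGroups(t))
  long <- data.frame(sample = rep(rownames(ct), ncol(ct)),
                     group = rep(grp, ncol(ct)),
                     gene = rep(colnames(ct), each = nrow(ct)),
                     ct = as.vector(ct))
  .writeTsv(long, path, meta)
  invisible(path)
}

#' Read a curated gene list (one symbol per line)
#'
#' Empty lines and `#` comments are skipped; whitespace is stripped.
#'
#' @param path file path.
#' @return Character vector of symbols.
#' @export
readGeneList <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Write a DE result table
#'
#' @param de consensus data.frame from [runDiffExpr()].
#' @param path file path.
#' @param meta header metadata.
#' @export
writeDEResult <- function(de, path, meta = character()) {
  .writeTsv(de, path, meta)
  invisible(path)
}
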