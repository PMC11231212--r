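# Disease relevance set: multi-source gene-disease-association voting and
# pathway over-representation (one-sided Fisher's exact test, BH-adjusted).

#' Relevance configuration
#'
#' @param min_sources minimum number of GDA sources in which a gene must
#'   appear to be selected (default 4 of 5).
#' @param alpha adjusted-p threshold for enriched pathways (default 0.01).
#' @param n_sources expected number of GDA source columns.
#' @return Object of class `relevance_config`.
#' @export
relevance_config <- function(min_sources = 4L, alpha = 0.01, n_sources = 5L) {
  stopifnot(min_sources >= 1L, min_sources <= n_sources,
            alpha > 0, alpha < 1)
  structure(list(min_sources = as.integer(min_sources), alpha = alpha,
                 n_sources = as.integer(n_sources)),
            class = "relevance_config")
}

#' Read a gene-disease-association presence matrix
#'
#' CSV with a header row: first column `gene`, then one 0/1 presence column
#' per source (PanelApp, Open Targets, Pharos, Geneshot and a knowledge-graph
#' export, in the reference workflow).
#'
#' @param path CSV file.
#' @return data.table with a `gene` column and one integer column per
#'   source.
#' @export
read_gda_matrix <- function(path) {
  m <- data.table::fread(path, header = TRUE)
  if (names(m)[1] != "gene") stop("first column of the GDA matrix must be 'gene'")
  if (anyDuplicated(m$gene)) stop("duplicate gene ids in GDA matrix")
  vals <- as.matrix(m[, -1])
  if (!all(vals %in% c(0L, 1L))) stop("GDA matrix cells must be 0/1")
  m
}

#' Select disease genes by multi-source voting
#'
#' A gene is selected when it is reported by at least `min_sources` of the
#' source columns.
#'
#' @param matrix GDA presence table from [read_gda_matrix()] (or an
#'   equivalent data.frame).
#' @param config a [relevance_config()].
#' @return Character vector of selected gene ids, sorted.
#' @export
select_gdas <- function(matrix, config = relevance_config()) {
  m <- data.table::as.data.table(matrix)
  src_cols <- setdiff(names(m), "gene")
  if (length(src_cols) != config$n_sources) {
    stop(sprintf("expected %d source columns, found %d",
                 config$n_sources, length(src_cols)))
  }
  votes <- rowSums(as.matrix(m[, src_cols, with = FALSE]))
  sort(m$gene[votes >= config$min_sources])
}

#' Read pathway gene sets in GMT format
#'
#' One pathway per line: id, description, then member gene ids, all
#' tab-separated. The gene universe is the union of all annotated genes.
#'
#' @param path GMT file.
#' @return List with `sets` (named list of gene-id vectors) and `universe`
#'   (character vector of all annotated genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line (need id, description, >=1 gene): ", l)
    sets[[f[1]]] <- unique(f[-c(1L, 2L)])
  }
  list(sets = sets, universe = sort(unique(unlist(sets, use.names = FALSE))))
}

#' One-sided Fisher's exact pathway over-representation
#'
#' For each pathway the 2x2 table (overlap k; query-only n - k; pathway-only
#' K - k; rest N - K - n + k) is tested for enrichment; the one-sided
#' p-value is the hypergeometric upper tail P(X >= k). Query genes outside
#' the annotation universe are dropped with a warning. The universe is the
#' set of genes carrying at least one pathway annotation.
#'
#' @param query_genes character vector of disease genes.
#' @param annotation list from [read_gmt()] (elements `sets`, `universe`).
#' @return data.table sorted by `p_value` with columns `pathway`, `k`, `K`,
#'   `n`, `N`, `p_value`, `p_adjusted` (BH across all tested pathways).
#' @export
enrich_pathways <- function(query_genes, annotation) {
  universe <- annotation$universe
  if (length(universe) == 0L) stop("empty annotation universe")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the annotation universe dropped",
                    length(outside)))
  }
  q <- intersect(query_genes, universe)
  N <- length(universe); n <- length(q)
  if (length(annotation$sets) == 0L) {
    return(data.table::data.table(pathway = character(), k = integer(),
                                  K = integer(), n = integer(), N = integer(),
                                  p_value = numeric(), p_adjusted = numeric()))
  }
  res <- data.table::rbindlist(lapply(names(annotation$sets), function(pw) {
    members <- intersect(annotation$sets[[pw]], universe)
    K <- length(members)
    k <- length(intersect(q, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(pathway = pw, k = k, K = K, n = n, N = N,
                           p_value = min(p, 1))
  }))
  res[, p_adjusted := bh_adjust(res$p_value)]
  data.table::setorder(res, p_value, pathway)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] (method `"BH"`): adjusted
#' values are monotone in the raw p-values, never smaller than them, and
#' returned in the input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Construct a relevance set
#'
#' @param genes character vector of curated disease gene ids.
#' @param pathways character vector of enriched pathway ids.
#' @param include,exclude optional manual override lists applied after the
#'   automatic selection (curated-evidence review): `include` ids are added
#'   to the gene set, `exclude` ids removed from both sets.
#' @return Object of class `relevance_set`.
#' @export
relevance_set <- function(genes = character(0), pathways = character(0),
                          include = character(0), exclude = character(0)) {
  genes <- setdiff(sort(unique(c(genes, include))), exclude)
  pathways <- setdiff(sort(unique(pathways)), exclude)
  structure(list(genes = genes, pathways = pathways), class = "relevance_set")
}

#' @export
print.relevance_set <- function(x, ...) {
  cat(sprintf("<relevance_set> %d gene(s), %d pathway(s)\n",
              length(x$genes), length(x$pathways)))
  invisible(x)
}

#' Build the disease relevance set from GDAs and enrichment results
#'
#' Genes are the multi-source-voted GDAs; pathways are those with a
#' BH-adjusted p-value below `alpha`.
#'
#' @param gdas character vector from [select_gdas()].
#' @param enrichment data.table from [enrich_pathways()].
#' @param config a [relevance_config()].
#' @param include,exclude manual override lists (see [relevance_set()]).
#' @return A [relevance_set()].
#' @export
build_relevance_set <- function(gdas, enrichment,
                                config = relevance_config(),
                                include = character(0),
                                exclude = character(0)) {
  pw <- if (nrow(enrichment) == 0L) character(0) else {
    enrichment$pathway[enrichment$p_adjusted < config$alpha]
  }
  relevance_set(genes = gdas, pathways = pw,
                include = include, exclude = exclude)
}

#' Write a relevance set as two plain-text id lists
#' @param relevance a [relevance_set()].
#' @param genes_path,pathways_path destination files (one id per line).
#' @return Invisibly, NULL.
#' @export
write_relevance_set <- function(relevance, genes_path, pathways_path) {
  writeLines(relevance$genes, genes_path)
  writeLines(relevance$pathways, pathways_path)
  invisible(NULL)
}

#' Read a relevance set written by [write_relevance_set()]
#' @param genes_path,pathways_path id-list files.
#' @return A [relevance_set()].
#' @export
read_relevance_set <- function(genes_path, pathways_path) {
  rl <- function(p) {
    if (!file.exists(p)) character(0) else {
      x <- readLines(p, warn = FALSE); x[nzchar(x)]
    }
  }
  relevance_set(genes = rl(genes_path), pathways = rl(pathways_path))
}
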