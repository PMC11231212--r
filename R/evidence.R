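# The automatic filtering cascade over evidence chains: rule filter ->
# rule grounding -> significant-path filter -> deductive path builder ->
# gene/pathway filter, with reduction reporting.

#' Filter cascade configuration
#'
#' Thresholds and relation sets for the four automatic filters. The
#' `treats` relation is the specific compound-disease link (approved-drug
#' space); trial-stage links (`in_trial_for`, `in_vivo_preclinical_trial_for`,
#' `has_orphan_designation_for`) are relaxed and may be replaced by `treats`
#' wherever the graph supports it. Ancestor and descendant disease-hierarchy
#' atoms share a single counter: more than `max_ancestor_atoms` of them make
#' a rule uninformative.
#'
#' @param max_ancestor_atoms maximum ancestor/descendant atoms per rule body.
#' @param max_relaxed_atoms maximum relaxed atoms per rule body.
#' @param relaxed_relations relation ids counted as relaxed.
#' @param ancestor_relations relation ids counted as disease-hierarchy atoms.
#' @param specific_relation the preferred compound-disease relation.
#' @param gene_pathway_mode `"strict"`, `"lenient"` or `"off"`.
#' @param drop_dominated_after_deduction remove chains dominated by the
#'   deduced canonical chain (default TRUE).
#' @param enable_rule_filter,enable_significant_filter,enable_deductive_builder
#'   stage toggles; the stage order itself is fixed.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(max_ancestor_atoms = 1L,
                          max_relaxed_atoms = 2L,
                          relaxed_relations = c("in_trial_for",
                                                "in_vivo_preclinical_trial_for",
                                                "has_orphan_designation_for"),
                          ancestor_relations = c("ancestor", "descendant",
                                                 "disease_disease_ancestor",
                                                 "disease_disease_descendant"),
                          specific_relation = "treats",
                          gene_pathway_mode = c("strict", "lenient", "off"),
                          drop_dominated_after_deduction = TRUE,
                          enable_rule_filter = TRUE,
                          enable_significant_filter = TRUE,
                          enable_deductive_builder = TRUE) {
  gene_pathway_mode <- match.arg(gene_pathway_mode)
  stopifnot(max_ancestor_atoms >= 0L, max_relaxed_atoms >= 0L)
  if (specific_relation %in% relaxed_relations) {
    stop("the specific relation cannot also be relaxed")
  }
  structure(list(max_ancestor_atoms = as.integer(max_ancestor_atoms),
                 max_relaxed_atoms = as.integer(max_relaxed_atoms),
                 relaxed_relations = relaxed_relations,
                 ancestor_relations = ancestor_relations,
                 specific_relation = specific_relation,
                 gene_pathway_mode = gene_pathway_mode,
                 drop_dominated_after_deduction = drop_dominated_after_deduction,
                 enable_rule_filter = enable_rule_filter,
                 enable_significant_filter = enable_significant_filter,
                 enable_deductive_builder = enable_deductive_builder),
            class = "filter_config")
}

#' Rule-based filtering: drop uninformative rule shapes
#'
#' A rule is discarded when its body contains more than
#' `max_ancestor_atoms` disease-hierarchy atoms (ancestor/descendant count
#' jointly) or more than `max_relaxed_atoms` relaxed trial-stage atoms.
#' Multiple hierarchy hops lose the disease of interest; chains built from
#' several trial-stage links describe speculative, frequently failing
#' programmes rather than treatments.
#'
#' @param rules a [rule_set()].
#' @param config a [filter_config()].
#' @return A [rule_set()] with only retained rules, order preserved.
#' @export
filter_rules <- function(rules, config = filter_config()) {
  keep <- vapply(rules$rules, function(r) {
    n_anc <- sum(r$relations %in% config$ancestor_relations)
    n_rel <- sum(r$relations %in% config$relaxed_relations)
    n_anc <= config$max_ancestor_atoms && n_rel <= config$max_relaxed_atoms
  }, logical(1))
  rule_set(rules$rules[keep], provenance = rules$provenance)
}

#' Ground a rule between a drug and a disease
#'
#' Returns every simple grounding of the rule body with the first variable
#' bound to `drug` and the last to `disease`, as evidence chains with
#' origin `"extracted"`.
#'
#' @param kg a `kgraph`.
#' @param rule a [kg_rule()].
#' @param drug,disease registered entity ids.
#' @return List of [evidence_chain()] (possibly empty), de-duplicated.
#' @export
ground_rule <- function(kg, rule, drug, disease) {
  if (!kg_has_entity(kg, drug)) stop("unknown entity id: ", drug)
  if (!kg_has_entity(kg, disease)) stop("unknown entity id: ", disease)
  n <- length(rule$relations)
  found <- list()
  walk <- function(node, nodes, i) {
    nb <- kg_neighbors(kg, node, relation = rule$relations[i],
                       direction = if (rule$forward[i]) "out" else "in")
    for (j in seq_len(nrow(nb))) {
      nxt <- nb$neighbor[j]
      if (nxt %in% nodes) next
      if (i == n) {
        if (identical(nxt, disease)) {
          found[[length(found) + 1L]] <<- evidence_chain(
            c(nodes, nxt), rule$relations, rule$forward,
            origin = "extracted", source_rules = format_rule(rule))
        }
      } else if (!identical(nxt, disease)) {
        walk(nxt, c(nodes, nxt), i + 1L)
      }
    }
  }
  walk(drug, drug, 1L)
  dedup_chains(found)
}

# TRUE when `a` is dominated by `b`: same node sequence, same orientation at
# every slot, and every relation either equal or relaxed-in-a vs specific-in-b,
# with at least one strict replacement.
chain_dominated_by <- function(a, b, config) {
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  if (!identical(a$forward, b$forward)) return(FALSE)
  strict <- FALSE
  for (i in seq_along(a$relations)) {
    if (a$relations[i] == b$relations[i]) next
    if (a$relations[i] %in% config$relaxed_relations &&
        b$relations[i] == config$specific_relation) {
      strict <- TRUE
    } else {
      return(FALSE)
    }
  }
  strict
}

#' Significant-path filtering: drop chains dominated by a more specific one
#'
#' Within a set of chains grounded for one (drug, disease) pair, a chain is
#' dropped when another chain with the identical node sequence replaces one
#' or more of its relaxed trial-stage edges by the specific `treats` edge
#' (same orientation) and matches it everywhere else.
#'
#' @param chains list of [evidence_chain()].
#' @param config a [filter_config()].
#' @return The retained chains, input order preserved.
#' @export
filter_significant_paths <- function(chains, config = filter_config()) {
  if (length(chains) <= 1L) return(chains)
  nkeys <- vapply(chains, chain_node_key, character(1))
  keep <- rep(TRUE, length(chains))
  for (i in seq_along(chains)) {
    mates <- which(nkeys == nkeys[i])
    for (j in mates) {
      if (j != i && chain_dominated_by(chains[[i]], chains[[j]], config)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  chains[keep]
}

#' Deductive path building: complete the most specific chain a group implies
#'
#' Chains are grouped by node sequence. For each group the canonical chain
#' uses, at every slot, the specific `treats` relation whenever the graph
#' contains it between that node pair in an orientation the group exhibits
#' at that slot; otherwise the slot keeps an existing relation (the
#' lexicographically first observed, forward orientation preferred, so the
#' construction is deterministic). When the canonical chain is not already
#' present it is added with origin `"deduced"`; when
#' `drop_dominated_after_deduction` is set, chains dominated by any chain in
#' the completed group are then removed.
#'
#' @param chains list of [evidence_chain()] for one (drug, disease) pair.
#' @param kg the `kgraph` the chains were grounded in.
#' @param config a [filter_config()].
#' @return The augmented (and possibly pruned) chain list.
#' @export
deduce_paths <- function(chains, kg, config = filter_config()) {
  if (length(chains) == 0L) return(chains)
  nkeys <- vapply(chains, chain_node_key, character(1))
  out <- list()
  for (key in unique(nkeys)) {
    group <- chains[nkeys == key]
    nodes <- group[[1]]$nodes
    n <- length(nodes) - 1L
    rels <- character(n); fwd <- logical(n)
    for (i in seq_len(n)) {
      a <- nodes[i]; b <- nodes[i + 1L]
      obs <- unique(data.table::data.table(
        relation = vapply(group, function(ch) ch$relations[i], character(1)),
        forward = vapply(group, function(ch) ch$forward[i], logical(1))))
      data.table::setorder(obs, relation, -forward)
      orients <- unique(obs$forward[order(!obs$forward)])  # forward first
      placed <- FALSE
      for (o in orients) {
        h <- if (o) a else b; t <- if (o) b else a
        if (kg_has_triple(kg, h, config$specific_relation, t)) {
          rels[i] <- config$specific_relation; fwd[i] <- o
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rels[i] <- obs$relation[1]; fwd[i] <- obs$forward[1]
      }
    }
    canonical <- evidence_chain(nodes, rels, fwd, origin = "deduced")
    have <- vapply(group, chain_key, character(1))
    if (!chain_key(canonical) %in% have) {
      group <- c(group, list(canonical))
    }
    if (isTRUE(config$drop_dominated_after_deduction)) {
      group <- filter_significant_paths(group, config)
    }
    out <- c(out, group)
  }
  out
}

#' Gene- and pathway-based filtering
#'
#' Keeps chains that touch the disease's biological relevance set. In
#' `"strict"` mode a chain survives only if at least one of its nodes is a
#' curated disease gene or an enriched pathway. `"lenient"` additionally
#' keeps chains that contain no Gene- or Pathway-typed node at all (so
#' purely clinical chains are not judged on biology they do not mention).
#' `"off"` keeps everything.
#'
#' @param chains list of [evidence_chain()].
#' @param relevance a [relevance_set()].
#' @param mode filtering mode; defaults to the config's
#'   `gene_pathway_mode`.
#' @param kg the `kgraph`, needed for node typing in lenient mode.
#' @return The retained chains.
#' @export
filter_gene_pathway <- function(chains, relevance,
                                mode = c("strict", "lenient", "off"),
                                kg = NULL) {
  mode <- match.arg(mode)
  if (mode == "off") return(chains)
  relevant_ids <- c(relevance$genes, relevance$pathways)
  if (mode == "strict" && length(relevant_ids) == 0L) {
    stop("strict gene/pathway filtering with an empty relevance set would discard every chain")
  }
  keep <- vapply(chains, function(ch) {
    if (any(ch$nodes %in% relevant_ids)) return(TRUE)
    if (mode == "lenient") {
      if (is.null(kg)) stop("lenient mode requires the knowledge graph for node typing")
      types <- kg_node_type(kg, ch$nodes)
      return(!any(types %in% c("Gene", "Pathway"), na.rm = TRUE))
    }
    FALSE
  }, logical(1))
  chains[keep]
}

#' Reduction report: path counts per pipeline stage
#'
#' @param all_paths exhaustive baseline path count.
#' @param anyburl_paths paths grounded from the learnt rules before
#'   filtering.
#' @param filtered_paths paths surviving the full cascade.
#' @return Object of class `reduction_report` with the three counts and the
#'   two percentage reductions `100 * (1 - filtered/anyburl)` and
#'   `100 * (1 - filtered/all)`.
#' @export
compute_reduction <- function(all_paths, anyburl_paths, filtered_paths) {
  counts <- c(all_paths, anyburl_paths, filtered_paths)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("path counts must be non-negative")
  }
  if (!(all_paths >= anyburl_paths && anyburl_paths >= filtered_paths)) {
    stop(sprintf("inconsistent counts: need all (%s) >= rule-derived (%s) >= filtered (%s)",
                 all_paths, anyburl_paths, filtered_paths))
  }
  structure(list(
    all_paths = all_paths,
    anyburl_paths = anyburl_paths,
    filtered_paths = filtered_paths,
    reduction_vs_anyburl = if (anyburl_paths == 0) 0 else 100 * (1 - filtered_paths / anyburl_paths),
    reduction_vs_all = if (all_paths == 0) 0 else 100 * (1 - filtered_paths / all_paths)
  ), class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf(paste0("<reduction_report> all: %s | rule-derived: %s | filtered: %s",
                     " | reduction vs rule-derived: %.1f%% | vs all: %.1f%%\n"),
              format(x$all_paths, big.mark = ","),
              format(x$anyburl_paths, big.mark = ","),
              format(x$filtered_paths, big.mark = ","),
              x$reduction_vs_anyburl, x$reduction_vs_all))
  invisible(x)
}

#' Run the full evidence-generation cascade for a set of predicted drugs
#'
#' Stage order is fixed: rule filter, rule grounding, significant-path
#' filter, deductive path builder, gene/pathway filter. Individual stages
#' can be disabled through the [filter_config()] toggles (gene/pathway via
#' `gene_pathway_mode = "off"`), but never reordered.
#'
#' @param kg a `kgraph`.
#' @param rules a [rule_set()].
#' @param drugs character vector of predicted compound ids (e.g. the top-n
#'   candidates from [rank_candidates()]).
#' @param disease disease entity id.
#' @param relevance a [relevance_set()] (may be NULL when the gene/pathway
#'   filter is off).
#' @param config a [filter_config()].
#' @param policy a [path_policy()] for the exhaustive baseline count.
#' @return List with `chains` (named list of chain lists per drug),
#'   `per_drug` (data.table of stage counts per drug: `all_paths` is the
#'   exhaustive baseline, `anyburl_paths` the unique chains grounded from
#'   the full unfiltered rule set, `filtered_paths` the survivors of the
#'   cascade), and `overall` (a [compute_reduction()] report over the
#'   summed counts).
#' @export
run_pipeline <- function(kg, rules, drugs, disease, relevance = NULL,
                         config = filter_config(), policy = path_policy()) {
  retained <- if (isTRUE(config$enable_rule_filter)) {
    filter_rules(rules, config)
  } else {
    rules
  }
  retained_texts <- vapply(retained$rules, format_rule, character(1))
  # the exhaustive baseline must cover at least the longest rule body,
  # otherwise rule-derived chains could outnumber the "all paths" count
  rule_len <- vapply(rules$rules, function(r) length(r$relations), integer(1))
  base_policy <- path_policy(max(policy$max_edges, rule_len, 1L),
                             policy$simple_paths_only)
  per_drug <- list()
  chains_out <- list()
  for (drug in drugs) {
    all_paths <- length(enumerate_paths(kg, drug, disease, base_policy))
    grounded <- list()
    for (r in rules$rules) {
      grounded <- c(grounded, ground_rule(kg, r, drug, disease))
    }
    grounded <- dedup_chains(grounded)
    n_grounded <- length(grounded)
    ch <- if (isTRUE(config$enable_rule_filter)) {
      Filter(function(c) any(c$source_rules %in% retained_texts), grounded)
    } else {
      grounded
    }
    if (isTRUE(config$enable_significant_filter)) {
      ch <- filter_significant_paths(ch, config)
    }
    n_significant <- length(ch)
    if (isTRUE(config$enable_deductive_builder)) {
      ch <- deduce_paths(ch, kg, config)
    }
    n_deduced <- length(ch)
    ch <- filter_gene_pathway(ch, relevance, mode = config$gene_pathway_mode,
                              kg = kg)
    chains_out[[drug]] <- ch
    per_drug[[drug]] <- data.table::data.table(
      drug = drug, all_paths = all_paths, anyburl_paths = n_grounded,
      after_significant = n_significant, after_deduction = n_deduced,
      filtered_paths = length(ch))
  }
  per_drug <- data.table::rbindlist(per_drug)
  overall <- compute_reduction(sum(per_drug$all_paths),
                               sum(per_drug$anyburl_paths),
                               sum(per_drug$filtered_paths))
  list(chains = chains_out, per_drug = per_drug, overall = overall)
}

#' Write a per-drug reduction report as TSV
#' @param per_drug data.table from [run_pipeline()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_reduction_report <- function(per_drug, path) {
  data.table::fwrite(per_drug, path, sep = "\t")
  invisible(path)
}
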