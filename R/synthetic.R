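# Seeded generator of meta-graph-shaped knowledge graphs with planted
# ground truth, plus exact fixtures for the printed worked examples.

#' Meta-graph of the synthetic knowledge graphs
#'
#' The relation vocabulary mirrors the printed biomedical relation names;
#' each row gives a relation and the node types it connects. `treats` and
#' the trial-stage relations link compounds to diseases (or phenotypes,
#' where treatments target symptoms).
#'
#' @return data.table with columns `relation`, `from_type`, `to_type`.
#' @export
kg_meta_graph <- function() {
  data.table::data.table(
    relation = c("treats", "treats", "in_trial_for",
                 "in_vivo_preclinical_trial_for", "has_orphan_designation_for",
                 "binds", "activates", "associates", "participates",
                 "involves", "involves", "presents", "ancestor", "descendant"),
    from_type = c("Compound", "Compound", "Compound", "Compound", "Compound",
                  "Compound", "Compound", "Disease", "Gene",
                  "Pathway", "Compound", "Disease", "Disease", "Disease"),
    to_type = c("Disease", "Phenotype", "Disease", "Disease", "Disease",
                "Gene", "Gene", "Gene", "Pathway",
                "Disease", "Pathway", "Phenotype", "Disease", "Disease")
  )
}

#' Synthetic knowledge-graph configuration
#'
#' Defaults describe a small but structurally faithful graph: all eight node
#' types are populated, background edges follow the meta-graph, and one
#' always-true treatment motif (compound binds a gene that a trial-stage
#' compound activates) is planted 20 times into the disease of interest.
#'
#' @param node_counts named integer vector, one entry per node type.
#' @param background_edges data.table (`relation`, `from_type`, `to_type`,
#'   `n`) of random edges to draw per meta-edge; NULL for the default.
#' @param motifs list of motif specs, each a list with `rule` (rule text),
#'   `n_instances`, `confidence` (fraction of instances whose head treats
#'   edge is planted) and `relevant` (whether its chains belong to the
#'   relevant manifest).
#' @param n_irrelevant number of planted double-ancestor (uninformative)
#'   chains.
#' @param curated_gene_fraction fraction of background genes marked curated
#'   in addition to all motif genes.
#' @param curated_pathway_fraction fraction of pathways marked curated.
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(node_counts = c(Compound = 40L, Disease = 12L,
                                             Gene = 30L, Protein = 5L,
                                             Pathway = 10L, Mechanism = 3L,
                                             ATC = 3L, Phenotype = 8L),
                             background_edges = NULL,
                             motifs = list(list(
                               rule = "treats(X,Y) <= binds(X,A), activates(B,A), in_trial_for(B,Y)",
                               n_instances = 20L, n_holdout = 10L,
                               confidence = 1.0, relevant = TRUE)),
                             n_irrelevant = 5L,
                             curated_gene_fraction = 0.2,
                             curated_pathway_fraction = 0.3,
                             seed = 1L) {
  if (any(node_counts < 0L)) stop("node counts must be non-negative")
  if (is.null(background_edges)) {
    background_edges <- kg_meta_graph()
    background_edges[, n := c(15L, 5L, 15L, 5L, 5L, 20L, 15L, 20L, 20L,
                              15L, 5L, 10L, 8L, 8L)]
  }
  for (m in motifs) {
    if (m$confidence < 0 || m$confidence > 1) stop("motif confidence must be in [0,1]")
    if (m$n_instances < 0L) stop("motif instance counts must be non-negative")
  }
  structure(list(node_counts = node_counts,
                 background_edges = background_edges,
                 motifs = motifs, n_irrelevant = as.integer(n_irrelevant),
                 curated_gene_fraction = curated_gene_fraction,
                 curated_pathway_fraction = curated_pathway_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# infer the node type of each rule variable by walking the body through the
# meta-graph, starting from the head relation's endpoint types
rule_var_types <- function(rule, meta = kg_meta_graph()) {
  head_row <- meta[meta$relation == rule$head_relation][1]
  if (nrow(head_row) == 0L || is.na(head_row$relation)) {
    stop("head relation absent from meta-graph: ", rule$head_relation)
  }
  n <- length(rule$relations)
  types <- rep(NA_character_, n + 1L)
  types[1] <- head_row$from_type
  types[n + 1L] <- head_row$to_type
  for (i in seq_len(n)) {
    rows <- meta[meta$relation == rule$relations[i]]
    if (nrow(rows) == 0L) stop("relation absent from meta-graph: ", rule$relations[i])
    src <- if (rule$forward[i]) rows$from_type else rows$to_type
    dst <- if (rule$forward[i]) rows$to_type else rows$from_type
    ok <- which(src == types[i])
    if (length(ok) == 0L) {
      stop(sprintf("motif infeasible: no meta-edge for %s leaving a %s node",
                   rule$relations[i], types[i]))
    }
    pick <- ok[1]
    if (i < n) {
      types[i + 1L] <- dst[pick]
    } else if (!any(dst[ok] == types[n + 1L])) {
      stop(sprintf("motif infeasible: %s cannot end on a %s node",
                   rule$relations[i], types[n + 1L]))
    }
  }
  types
}

#' Generate a synthetic knowledge graph with planted ground truth
#'
#' Emits a typed graph honouring the meta-graph, with random background
#' edges, planted rule motifs whose head `treats` edges form the held-out
#' treatment list, planted uninformative double-ancestor chains, and
#' curated gene/pathway sets. All randomness is driven by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List with `kg` (a `kgraph`) and `truth`, a ground-truth manifest:
#'   `rules` (planted rule texts with configured confidence), `disease`
#'   (target disease id), `planted_treats` (data.table of held-out treats
#'   triples), `curated_genes`, `curated_pathways`, `relevant_chains` and
#'   `irrelevant_chains` (lists of [evidence_chain()]).
#' @export
generate_kg <- function(config = synthetic_config()) {
  set.seed(config$seed)
  meta <- kg_meta_graph()
  counts <- config$node_counts
  ids_of <- list()
  ent <- list()
  for (tp in names(counts)) {
    nn <- counts[[tp]]
    ids <- if (nn > 0L) sprintf("%s_%03d", tolower(tp), seq_len(nn)) else character(0)
    ids_of[[tp]] <- ids
    if (nn > 0L) {
      ent[[tp]] <- data.table::data.table(id = ids, node_type = tp, label = ids)
    }
  }
  triples <- list()
  add_triple <- function(h, r, t) {
    triples[[length(triples) + 1L]] <<- data.table::data.table(
      head = h, relation = r, tail = t)
  }
  # background edges per meta-edge
  bg <- config$background_edges
  target_disease <- if (length(ids_of$Disease)) ids_of$Disease[1] else NA_character_
  for (i in seq_len(nrow(bg))) {
    src <- ids_of[[bg$from_type[i]]]; dst <- ids_of[[bg$to_type[i]]]
    # keep the disease of interest free of background treats edges so the
    # held-out treatment list coincides with the planted manifest
    if (bg$relation[i] == "treats" && bg$to_type[i] == "Disease" &&
        !is.na(target_disease)) {
      dst <- setdiff(dst, target_disease)
    }
    nreq <- bg$n[i]
    if (nreq == 0L || length(src) == 0L || length(dst) == 0L) next
    h <- sample(src, nreq, replace = TRUE)
    t <- sample(dst, nreq, replace = TRUE)
    ok <- h != t
    add_triple(h[ok], rep(bg$relation[i], sum(ok)), t[ok])
  }
  disease <- if (length(ids_of$Disease)) ids_of$Disease[1] else NA_character_
  extra_ent <- list()
  new_entity <- function(id, tp) {
    extra_ent[[length(extra_ent) + 1L]] <<- data.table::data.table(
      id = id, node_type = tp, label = id)
    id
  }
  planted_rules <- list()
  planted_treats <- list()
  relevant_chains <- list()
  motif_genes <- character(0)
  parsed_motifs <- list()
  planted_pairs <- list()
  for (mi in seq_along(config$motifs)) {
    spec <- config$motifs[[mi]]
    rule <- parse_rule(spec$rule)
    parsed_motifs[[mi]] <- rule
    vtypes <- rule_var_types(rule, meta)
    if (is.na(disease)) stop("motif planting requires at least one Disease node")
    n_hold <- spec$n_holdout %||% 0L
    other_diseases <- setdiff(ids_of$Disease, disease)
    if (spec$n_instances > 0L && length(other_diseases) == 0L) {
      stop("training motif instances need at least two Disease nodes")
    }
    # held-out instances always carry their head edge (it is what gets
    # removed and re-predicted), so the training-instance head count is
    # chosen to hit the configured confidence over all planted instances
    n_head <- max(0L, round(spec$confidence * (spec$n_instances + n_hold)) - n_hold)
    for (ii in seq_len(spec$n_instances + n_hold)) {
      holdout <- ii > spec$n_instances
      # training instances support the rule on other diseases; held-out
      # instances connect fresh drugs to the disease of interest, whose
      # head edges are later removed and must be re-predicted
      y <- if (holdout) disease else sample(other_diseases, 1L)
      vn <- length(vtypes)
      nodes <- character(vn)
      nodes[vn] <- y
      for (vi in seq_len(vn - 1L)) {
        nodes[vi] <- new_entity(sprintf("m%d_i%02d_v%d_%s", mi, ii, vi,
                                        tolower(vtypes[vi])), vtypes[vi])
      }
      for (ai in seq_along(rule$relations)) {
        a <- nodes[ai]; b <- nodes[ai + 1L]
        if (rule$forward[ai]) add_triple(a, rule$relations[ai], b)
        else add_triple(b, rule$relations[ai], a)
      }
      planted_pairs[[length(planted_pairs) + 1L]] <- data.table::data.table(
        motif = mi, x = nodes[1], y = y)
      if (holdout || ii <= n_head) {
        add_triple(nodes[1], rule$head_relation, y)
        if (holdout) {
          planted_treats[[length(planted_treats) + 1L]] <- data.table::data.table(
            head = nodes[1], relation = rule$head_relation, tail = y)
        }
      }
      if (holdout && isTRUE(spec$relevant)) {
        relevant_chains[[length(relevant_chains) + 1L]] <- evidence_chain(
          nodes, rule$relations, rule$forward, origin = "extracted",
          source_rules = spec$rule)
      }
      motif_genes <- c(motif_genes, nodes[vtypes == "Gene"])
    }
    planted_rules[[length(planted_rules) + 1L]] <-
      list(rule = spec$rule, confidence = spec$confidence,
           n_instances = spec$n_instances, n_holdout = n_hold)
  }
  # planted uninformative chains: two disease-hierarchy hops between the
  # treated disease and the disease of interest
  irrelevant_chains <- list()
  irr_rule <- "treats(X,Y) <= treats(X,A), ancestor(B,A), ancestor(B,Y)"
  holdout_drugs <- unique(vapply(planted_treats, function(p) p$head, character(1)))
  for (ii in seq_len(config$n_irrelevant)) {
    # attach uninformative chains to held-out drugs where possible, so the
    # filter cascade actually encounters them during evidence generation
    x <- if (length(holdout_drugs)) {
      holdout_drugs[((ii - 1L) %% length(holdout_drugs)) + 1L]
    } else {
      new_entity(sprintf("irr_i%02d_compound", ii), "Compound")
    }
    d1 <- new_entity(sprintf("irr_i%02d_disease_a", ii), "Disease")
    d2 <- new_entity(sprintf("irr_i%02d_disease_b", ii), "Disease")
    add_triple(x, "treats", d1)
    add_triple(d2, "ancestor", d1)
    add_triple(d2, "ancestor", disease)
    irrelevant_chains[[length(irrelevant_chains) + 1L]] <- evidence_chain(
      c(x, d1, d2, disease), c("treats", "ancestor", "ancestor"),
      c(TRUE, FALSE, TRUE), origin = "extracted", source_rules = irr_rule)
  }
  empty_tr <- data.table::data.table(head = character(), relation = character(),
                                     tail = character())
  tr <- if (length(triples)) unique(data.table::rbindlist(triples)) else empty_tr
  # saturate: accidental body groundings of a planted rule (via background
  # edges) would dilute its confidence below the configured value, so each
  # accidental endpoint pair receives the head edge with that probability
  for (mi in seq_along(parsed_motifs)) {
    spec <- config$motifs[[mi]]
    rule <- parsed_motifs[[mi]]
    pairs <- rule_body_pairs(tr, rule)
    if (nrow(pairs) == 0L) next
    heads <- tr[tr$relation == rule$head_relation, c("head", "tail")]
    data.table::setnames(heads, c("x", "y"))
    accidental <- pairs[!heads, on = c("x", "y")]
    # intentionally headless training instances are part of the configured
    # confidence, not accidents; leave them alone
    own <- data.table::rbindlist(planted_pairs)
    if (nrow(own) > 0L) {
      accidental <- accidental[!own[own$motif == mi, c("x", "y")],
                               on = c("x", "y")]
    }
    for (j in seq_len(nrow(accidental))) {
      if (stats::runif(1) < spec$confidence) {
        new_edge <- data.table::data.table(head = accidental$x[j],
                                           relation = rule$head_relation,
                                           tail = accidental$y[j])
        tr <- rbind(tr, new_edge)
        if (accidental$y[j] == disease) {
          planted_treats[[length(planted_treats) + 1L]] <- new_edge
        }
      }
    }
    tr <- unique(tr)
  }
  ents <- if (length(ent) + length(extra_ent)) {
    data.table::rbindlist(c(ent, extra_ent))
  } else {
    data.table::data.table(id = character(), node_type = character(),
                           label = character())
  }
  motif_genes <- unique(motif_genes)
  bg_genes <- ids_of$Gene
  n_cur <- round(config$curated_gene_fraction * length(bg_genes))
  curated_genes <- sort(unique(c(motif_genes,
                                 if (n_cur > 0L) sample(bg_genes, n_cur))))
  n_cpw <- round(config$curated_pathway_fraction * length(ids_of$Pathway))
  curated_pathways <- sort(if (n_cpw > 0L) sample(ids_of$Pathway, n_cpw) else character(0))
  kg <- kgraph(tr, ents)
  truth <- list(
    rules = planted_rules,
    disease = disease,
    planted_treats = if (length(planted_treats)) {
      unique(data.table::rbindlist(planted_treats))
    } else {
      data.table::data.table(head = character(), relation = character(),
                             tail = character())
    },
    curated_genes = curated_genes,
    curated_pathways = curated_pathways,
    relevant_chains = relevant_chains,
    irrelevant_chains = irrelevant_chains,
    irrelevant_rule = irr_rule
  )
  list(kg = kg, truth = truth)
}

#' Write a synthetic graph and its manifest to disk
#'
#' Emits the triples/node-type TSVs consumed by [load_triples()] and the
#' ground-truth manifest as JSON.
#'
#' @param sim list from [generate_kg()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_synthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_triples(sim$kg, file.path(dir, "triples.tsv"),
                file.path(dir, "node_types.tsv"))
  truth <- sim$truth
  manifest <- list(
    rules = truth$rules,
    disease = truth$disease,
    planted_treats = truth$planted_treats,
    curated_genes = truth$curated_genes,
    curated_pathways = truth$curated_pathways,
    relevant_chains = lapply(truth$relevant_chains, unclass),
    irrelevant_chains = lapply(truth$irrelevant_chains, unclass),
    irrelevant_rule = truth$irrelevant_rule
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Worked example: four trial/treatment paths between a drug and a disease
#'
#' A six-triple graph in which Levofloxacin and Dornase alfa each both treat
#' and are in trial for Bronchitis, and Dornase alfa both treats and is in
#' trial for Cystic fibrosis. Four extracted chains connect Levofloxacin to
#' Cystic fibrosis through Bronchitis and Dornase alfa; the all-`treats`
#' chain is absent and is exactly what the deductive path builder recovers.
#'
#' @return List with `kg` (a `kgraph`) and `chains` (the four extracted
#'   [evidence_chain()]s).
#' @export
levofloxacin_fixture <- function() {
  ents <- data.table::data.table(
    id = c("Levofloxacin", "Dornase_alfa", "Bronchitis", "Cystic_fibrosis"),
    node_type = c("Compound", "Compound", "Disease", "Disease"))
  tr <- data.table::data.table(
    head = c("Levofloxacin", "Levofloxacin", "Dornase_alfa", "Dornase_alfa",
             "Dornase_alfa", "Dornase_alfa"),
    relation = c("treats", "in_trial_for", "treats", "in_trial_for",
                 "treats", "in_trial_for"),
    tail = c("Bronchitis", "Bronchitis", "Bronchitis", "Bronchitis",
             "Cystic_fibrosis", "Cystic_fibrosis"))
  kg <- kgraph(tr, ents)
  nodes <- c("Levofloxacin", "Bronchitis", "Dornase_alfa", "Cystic_fibrosis")
  mk <- function(r1, r2, r3) {
    evidence_chain(nodes, c(r1, r2, r3), c(TRUE, FALSE, TRUE),
                   origin = "extracted")
  }
  chains <- list(
    mk("in_trial_for", "treats", "in_trial_for"),
    mk("in_trial_for", "treats", "treats"),
    mk("treats", "treats", "in_trial_for"),
    mk("treats", "in_trial_for", "treats"))
  list(kg = kg, chains = chains)
}

#' Worked example: a treats / in-trial-for chain pair for the significant-path filter
#'
#' Two chains over the [levofloxacin_fixture()] graph that share every node
#' and differ only in the drug-to-Bronchitis edge: one uses `treats`, the
#' other the relaxed `in_trial_for`. The significant-path filter keeps the
#' former and drops the latter.
#'
#' @return List with `kg`, `kept` and `dropped`.
#' @export
fig5_chain_pair <- function() {
  fx <- levofloxacin_fixture()
  nodes <- c("Levofloxacin", "Bronchitis", "Dornase_alfa", "Cystic_fibrosis")
  kept <- evidence_chain(nodes, c("treats", "treats", "in_trial_for"),
                         c(TRUE, FALSE, TRUE), origin = "extracted")
  dropped <- evidence_chain(nodes, c("in_trial_for", "treats", "in_trial_for"),
                            c(TRUE, FALSE, TRUE), origin = "extracted")
  list(kg = fx$kg, kept = kept, dropped = dropped)
}

#' Worked example: a compound potentiating a bound target
#'
#' The three-edge chain Lumacaftor -binds-> CFTR <-activates- potentiator
#' -in_trial_for-> Cystic fibrosis, optionally with the head `treats` edge
#' between Lumacaftor and the disease.
#'
#' @param include_head also add the `treats` head triple (default FALSE, so
#'   the raw fixture has exactly 3 triples and 4 entities).
#' @return A `kgraph`.
#' @export
lumacaftor_fixture <- function(include_head = FALSE) {
  ents <- data.table::data.table(
    id = c("Lumacaftor", "CFTR", "CFTR_potentiator", "Cystic_fibrosis"),
    node_type = c("Compound", "Gene", "Compound", "Disease"))
  tr <- data.table::data.table(
    head = c("Lumacaftor", "CFTR_potentiator", "CFTR_potentiator"),
    relation = c("binds", "activates", "in_trial_for"),
    tail = c("CFTR", "CFTR", "Cystic_fibrosis"))
  if (include_head) {
    tr <- rbind(tr, data.table::data.table(
      head = "Lumacaftor", relation = "treats", tail = "Cystic_fibrosis"))
  }
  kgraph(tr, ents)
}

#' The printed worked-example rules
#'
#' Seven rules: five body shapes ranging from disease-hierarchy hops to
#' gene/pathway mechanisms, plus the two shapes the rule filter is designed
#' to discard (a double-ancestor rule and a triple trial-stage rule).
#' Confidences are unset.
#'
#' @return A [rule_set()] of 7 rules; the two discardable ones are last.
#' @export
printed_rule_fixtures <- function() {
  texts <- c(
    "treats(X,Y) <= treats(X,A), descendant(Y,A)",
    "treats(X,Y) <= treats(X,A), ancestor(A,Y)",
    "treats(X,Y) <= binds(X,A), participates(A,B), involves(B,Y)",
    "treats(X,Y) <= involves(X,A), involves(A,B), ancestor(B,Y)",
    "treats(X,Y) <= treats(X,A), associates(A,B), associates(C,B), ancestor(C,Y)",
    "treats(X,Y) <= treats(X,A), presents(B,A), ancestor(C,B), ancestor(C,Y)",
    "treats(X,Y) <= in_trial_for(X,A), in_trial_for(B,A), in_trial_for(B,Y)")
  rule_set(lapply(texts, parse_rule))
}
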