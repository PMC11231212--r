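test_that("the rule filter discards double-hierarchy and triple-trial rules only", {
  rules <- printed_rule_fixtures()
  kept <- filter_rules(rules)
  kept_texts <- vapply(kept$rules, format_rule, character(1))
  all_texts <- vapply(rules$rules, format_rule, character(1))
  expect_length(kept, 5L)
  expect_identical(kept_texts, all_texts[1:5])
  dropped <- setdiff(all_texts, kept_texts)
  expect_true(any(grepl("ancestor.*ancestor", dropped)))
  expect_true(any(grepl("in_trial_for.*in_trial_for.*in_trial_for", dropped)))
  # thresholds are configurable
  lax <- filter_config(max_ancestor_atoms = 2L, max_relaxed_atoms = 3L)
  expect_length(filter_rules(rules, lax), 7L)
  expect_error(filter_config(specific_relation = "in_trial_for"), "relaxed")
})

test_that("grounding a rule yields exactly the simple body instantiations", {
  kg <- lumacaftor_fixture(include_head = TRUE)
  r <- parse_rule("treats(X,Y) <= binds(X,A), activates(B,A), in_trial_for(B,Y)")
  chains <- ground_rule(kg, r, "Lumacaftor", "Cystic_fibrosis")
  expect_length(chains, 1L)
  expect_identical(chains[[1]]$nodes,
                   c("Lumacaftor", "CFTR", "CFTR_potentiator", "Cystic_fibrosis"))
  expect_identical(chains[[1]]$origin, "extracted")
  expect_identical(chains[[1]]$source_rules, format_rule(r))
  # rule relation absent from the graph
  r2 <- parse_rule("treats(X,Y) <= participates(X,A), involves(A,Y)")
  expect_length(ground_rule(kg, r2, "Lumacaftor", "Cystic_fibrosis"), 0L)
})

test_that("grounding matches brute-force assignment enumeration on random graphs", {
  for (seed in 201:260) {
    kg <- random_kg(seed, n_nodes = sample(6:30, 1L))
    edges <- as.data.frame(kg$triples)
    rule <- random_rule(kg)
    pair <- sample(kg$entities$id, 2L)
    got <- ground_rule(kg, rule, pair[1], pair[2])
    want <- oracle_groundings(edges, rule, pair[1], pair[2])
    expect_identical(chain_keys(got), want,
                     info = paste("seed", seed, format_rule(rule)))
  }
})

test_that("path enumeration matches the brute-force oracle on random graphs", {
  for (seed in 301:380) {
    kg <- random_kg(seed, n_nodes = sample(5:30, 1L))
    edges <- as.data.frame(kg$triples)
    pair <- sample(kg$entities$id, 2L)
    max_edges <- sample(1:3, 1L)
    got <- enumerate_paths(kg, pair[1], pair[2], path_policy(max_edges))
    expect_identical(chain_keys(got),
                     oracle_paths(edges, pair[1], pair[2], max_edges),
                     info = paste("seed", seed, max_edges))
  }
})

test_that("the significant-path filter drops the trial variant of a treats chain", {
  p <- fig5_chain_pair()
  out <- filter_significant_paths(list(p$dropped, p$kept))
  expect_length(out, 1L)
  expect_identical(out[[1]]$relations[1], "treats")
  # a chain with no relaxed edges is always kept
  solo <- evidence_chain(c("a", "b"), "treats", TRUE)
  expect_length(filter_significant_paths(list(solo)), 1L)
  # a relaxed chain without a dominating partner is kept
  lone <- evidence_chain(c("a", "b"), "in_trial_for", TRUE)
  other_nodes <- evidence_chain(c("a", "c"), "treats", TRUE)
  expect_length(filter_significant_paths(list(lone, other_nodes)), 2L)
})

test_that("domination matches a pairwise oracle over all chain pairs", {
  cfg <- filter_config()
  rels <- c("treats", "in_trial_for", "binds", "has_orphan_designation_for")
  set.seed(77)
  for (rep in 1:40) {
    n_edges <- sample(2:3, 1L)
    nodes <- paste0("n", 1:(n_edges + 1L))
    chains <- lapply(1:6, function(i) {
      evidence_chain(nodes, sample(rels, n_edges, replace = TRUE),
                     rep(TRUE, n_edges))
    })
    chains <- dedup_chains(chains)
    got <- chain_keys(filter_significant_paths(chains, cfg))
    # oracle: drop chain i iff some j differs only by relaxed -> treats
    dominated <- vapply(seq_along(chains), function(i) {
      any(vapply(seq_along(chains), function(j) {
        if (i == j) return(FALSE)
        a <- chains[[i]]$relations; b <- chains[[j]]$relations
        diff <- which(a != b)
        length(diff) > 0 &&
          all(a[diff] %in% cfg$relaxed_relations & b[diff] == "treats")
      }, logical(1)))
    }, logical(1))
    expect_identical(got, chain_keys(chains[!dominated]), info = paste("rep", rep))
  }
})

test_that("the deductive builder completes the all-treats chain", {
  fx <- levofloxacin_fixture()
  cfg <- filter_config(drop_dominated_after_deduction = FALSE)
  out <- deduce_paths(fx$chains, fx$kg, cfg)
  expect_length(out, 5L)
  deduced <- Filter(function(ch) ch$origin == "deduced", out)
  expect_length(deduced, 1L)
  expect_identical(deduced[[1]]$relations, c("treats", "treats", "treats"))
  expect_true(chain_in_kg(fx$kg, deduced[[1]]))
  # single all-specific chain is a fixpoint
  solo <- deduced
  expect_identical(chain_keys(deduce_paths(solo, fx$kg, cfg)), chain_keys(solo))
})

test_that("deduction only uses graph-supported substitutions", {
  # treats is available for slot 1 but not slot 3: only slot 1 upgrades
  tr <- data.frame(head = c("c", "c", "d", "d"),
                   relation = c("in_trial_for", "treats", "treats",
                                "in_trial_for"),
                   tail = c("B", "B", "B", "CF"))
  nt <- data.frame(id = c("c", "d", "B", "CF"),
                   node_type = c("Compound", "Compound", "Disease", "Disease"))
  kg <- kgraph(tr, nt)
  ch <- evidence_chain(c("c", "B", "d", "CF"),
                       c("in_trial_for", "treats", "in_trial_for"),
                       c(TRUE, FALSE, TRUE))
  out <- deduce_paths(list(ch), kg,
                      filter_config(drop_dominated_after_deduction = FALSE))
  added <- Filter(function(x) x$origin == "deduced", out)
  expect_length(added, 1L)
  expect_identical(added[[1]]$relations,
                   c("treats", "treats", "in_trial_for"))
  expect_true(chain_in_kg(kg, added[[1]]))
  # with domination removal the relaxed original is pruned
  out2 <- deduce_paths(list(ch), kg, filter_config())
  expect_length(out2, 1L)
  expect_identical(out2[[1]]$origin, "deduced")
})

test_that("gene/pathway filtering honours strict, lenient and off modes", {
  nt <- data.frame(id = c("drug", "CFTR", "g2", "D1", "D2", "pw"),
                   node_type = c("Compound", "Gene", "Gene", "Disease",
                                 "Disease", "Pathway"))
  tr <- data.frame(head = c("drug", "drug", "drug", "D1", "pw"),
                   relation = c("binds", "binds", "treats", "ancestor", "involves"),
                   tail = c("CFTR", "g2", "D1", "D2", "D2"))
  kg <- kgraph(tr, nt)
  rel <- relevance_set(genes = "CFTR", pathways = character(0))
  curated <- evidence_chain(c("drug", "CFTR"), "binds", TRUE)
  uncurated <- evidence_chain(c("drug", "g2"), "binds", TRUE)
  clinical <- evidence_chain(c("drug", "D1", "D2"), c("treats", "ancestor"),
                             c(TRUE, TRUE))
  chains <- list(curated, uncurated, clinical)
  strict <- filter_gene_pathway(chains, rel, "strict", kg)
  expect_identical(chain_keys(strict), chain_keys(list(curated)))
  lenient <- filter_gene_pathway(chains, rel, "lenient", kg)
  expect_identical(chain_keys(lenient), chain_keys(list(curated, clinical)))
  expect_identical(filter_gene_pathway(chains, rel, "off"), chains)
  expect_error(filter_gene_pathway(chains, relevance_set(), "strict", kg),
               "empty relevance")
})

test_that("reduction arithmetic and validation match the definitions", {
  r <- compute_reduction(100, 40, 10)
  expect_equal(r$reduction_vs_anyburl, 75)
  expect_equal(r$reduction_vs_all, 90)
  expect_equal(compute_reduction(50, 40, 40)$reduction_vs_anyburl, 0)
  expect_equal(compute_reduction(10, 0, 0)$reduction_vs_anyburl, 0)
  expect_error(compute_reduction(10, 20, 5), "inconsistent")
  expect_error(compute_reduction(-1, 0, 0), "non-negative")
})

test_that("the full cascade keeps planted relevant chains and removes planted noise", {
  sim <- generate_kg(synthetic_config(seed = 42))
  rem <- remove_target_edges(sim$kg, sim$truth$disease, "treats")
  rules <- learn_rules(rem$kg, learner_config(iterations = 250L, seed = 7L))
  # include the uninformative double-ancestor rule so its chains are offered
  irr <- parse_rule(sim$truth$irrelevant_rule)
  irr$confidence <- 0.05
  rules <- rule_set(c(rules$rules, list(irr)))
  rel <- relevance_set(genes = sim$truth$curated_genes,
                       pathways = sim$truth$curated_pathways)
  drugs <- unique(sim$truth$planted_treats$head)
  res <- run_pipeline(rem$kg, rules, drugs, sim$truth$disease, rel)
  final <- unlist(lapply(res$chains, chain_keys))
  expect_true(all(vapply(sim$truth$relevant_chains, chain_key, character(1))
                  %in% final))
  expect_false(any(vapply(sim$truth$irrelevant_chains, chain_key, character(1))
                   %in% final))
  # monotone contraction across stages
  expect_true(all(res$per_drug$filtered_paths <= res$per_drug$after_deduction))
  expect_true(all(res$per_drug$after_significant <= res$per_drug$anyburl_paths))
  expect_true(all(res$per_drug$anyburl_paths <= res$per_drug$all_paths))
  # disabling everything returns the raw grounding union
  cfg_off <- filter_config(gene_pathway_mode = "off", enable_rule_filter = FALSE,
                           enable_significant_filter = FALSE,
                           enable_deductive_builder = FALSE)
  res_off <- run_pipeline(rem$kg, rules, drugs, sim$truth$disease, NULL, cfg_off)
  expect_identical(res_off$per_drug$filtered_paths, res_off$per_drug$anyburl_paths)
  # empty rule set
  res_empty <- run_pipeline(rem$kg, rule_set(), drugs[1], sim$truth$disease,
                            NULL, cfg_off)
  expect_equal(res_empty$overall$anyburl_paths, 0)
  expect_length(res_empty$chains[[1]], 0L)
})

test_that("the filter cascade is idempotent", {
  fx <- levofloxacin_fixture()
  cfg <- filter_config(gene_pathway_mode = "off")
  once <- deduce_paths(filter_significant_paths(fx$chains, cfg), fx$kg, cfg)
  twice <- deduce_paths(filter_significant_paths(once, cfg), fx$kg, cfg)
  expect_identical(chain_keys(twice), chain_keys(once))
})

test_that("chains survive JSON-lines round-trips with provenance intact", {
  fx <- levofloxacin_fixture()
  path <- withr::local_tempfile()
  write_chains(fx$chains, path)
  back <- read_chains(path)
  expect_identical(chain_keys(back), chain_keys(fx$chains))
  expect_identical(back[[1]]$origin, "extracted")
})
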