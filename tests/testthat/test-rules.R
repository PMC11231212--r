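printed_rule_texts <- c(
  "treats(X,Y) <= treats(X,A), descendant(Y,A)",
  "treats(X,Y) <= treats(X,A), ancestor(A,Y)",
  "treats(X,Y) <= binds(X,A), participates(A,B), involves(B,Y)",
  "treats(X,Y) <= involves(X,A), involves(A,B), ancestor(B,Y)",
  "treats(X,Y) <= treats(X,A), associates(A,B), associates(C,B), ancestor(C,Y)",
  "treats(X,Y) <= treats(X,A), presents(B,A), ancestor(C,B), ancestor(C,Y)",
  "treats(X,Y) <= in_trial_for(X,A), in_trial_for(B,A), in_trial_for(B,Y)")

test_that("rule text parses and re-renders identically, atoms oriented correctly", {
  for (txt in printed_rule_texts) {
    r <- parse_rule(txt)
    expect_identical(format_rule(r), txt)
  }
  r <- parse_rule("treats(X,Y) <= binds(X,A), activates(B,A), in_trial_for(B,Y)")
  expect_identical(r$relations, c("binds", "activates", "in_trial_for"))
  expect_identical(r$forward, c(TRUE, FALSE, TRUE))
  expect_identical(parse_rule("treats(X,Y) <= r(X,Y)")$forward, TRUE)
  expect_error(parse_rule("treats(X,Y)"), "<=")
  expect_error(parse_rule("treats(X,Y) <= r(A,B)"), "chain")
})

test_that("generalize replaces nodes by variables, preserving orientation", {
  gp <- evidence_chain(c("Lumacaftor", "CFTR", "CFTR_potentiator", "Cystic_fibrosis"),
                       c("binds", "activates", "in_trial_for"),
                       c(TRUE, FALSE, TRUE))
  r <- generalize(gp, "treats")
  expect_identical(format_rule(r),
                   "treats(X,Y) <= binds(X,A), activates(B,A), in_trial_for(B,Y)")
  # 1-edge ground path
  gp1 <- evidence_chain(c("a", "b"), "r", TRUE)
  expect_identical(format_rule(generalize(gp1, "treats")),
                   "treats(X,Y) <= r(X,Y)")
  # same relation/orientation sequence generalizes identically (dedup key)
  gp2 <- evidence_chain(c("u", "v", "w", "z"),
                        c("binds", "activates", "in_trial_for"),
                        c(TRUE, FALSE, TRUE))
  expect_identical(format_rule(generalize(gp2, "treats")), format_rule(r))
})

test_that("sampling a ground path finds the unique route deterministically", {
  kg <- lumacaftor_fixture(include_head = TRUE)
  set.seed(5)
  gp <- sample_ground_path(kg, "treats", max_edges = 3L, walk_attempts = 20L)
  expect_false(is.null(gp))
  expect_identical(gp$nodes, c("Lumacaftor", "CFTR", "CFTR_potentiator",
                               "Cystic_fibrosis"))
  expect_identical(gp$relations, c("binds", "activates", "in_trial_for"))
  # fixed seed, fixed graph: identical output
  set.seed(17)
  a <- sample_ground_path(kg, "treats", 3L, 20L)
  set.seed(17)
  b <- sample_ground_path(kg, "treats", 3L, 20L)
  expect_identical(a, b)
  expect_error(sample_ground_path(kg, "no_such_rel"), "target relation")
})

test_that("score_rule computes support/body_count/confidence as defined", {
  # planted: every body-satisfying pair also has the head edge
  tr <- data.frame(
    head = c(paste0("c", 1:4), paste0("c", 1:4)),
    relation = c(rep("binds", 4), rep("treats", 4)),
    tail = c(paste0("g", 1:4), paste0("d", c(1, 1, 2, 2))))
  tr$tail[1:4] <- paste0("g", c(1, 1, 2, 2))
  tr2 <- data.frame(head = paste0("g", 1:2), relation = "involves",
                    tail = paste0("d", 1:2))
  tr <- rbind(tr, tr2)
  nt <- data.frame(id = c(paste0("c", 1:4), paste0("g", 1:2), paste0("d", 1:2)),
                   node_type = c(rep("Compound", 4), rep("Gene", 2),
                                 rep("Disease", 2)))
  kg <- kgraph(tr, nt)
  r <- score_rule(kg, parse_rule("treats(X,Y) <= binds(X,A), involves(A,Y)"))
  expect_equal(r$body_count, 4L)
  expect_equal(r$support, 4L)
  expect_equal(r$confidence, 1.0)
  # arithmetic: support 3, body 10, smoothing 0 -> 0.3
  rr <- kg_rule("treats", "r", TRUE, support = 3L, body_count = 10L)
  rr$confidence <- rr$support / (rr$body_count + 0)
  expect_equal(rr$confidence, 0.3)
  # smoothing strictly decreases confidence
  rs <- score_rule(kg, parse_rule("treats(X,Y) <= binds(X,A), involves(A,Y)"),
                   smoothing = 1)
  expect_lt(rs$confidence, r$confidence)
  # unscorable body
  ru <- score_rule(kg, parse_rule("treats(X,Y) <= participates(X,Y)"))
  expect_equal(ru$body_count, 0L)
  expect_true(is.na(ru$confidence))
})

test_that("scoring matches exhaustive assignment enumeration on random graphs", {
  for (seed in 1:60) {
    kg <- random_kg(seed, n_nodes = sample(5:25, 1L))
    edges <- as.data.frame(kg$triples)
    rule <- random_rule(kg)
    got <- score_rule(kg, rule)
    want <- oracle_score(edges, rule)
    expect_equal(got$body_count, want$body_count,
                 info = paste("seed", seed, format_rule(rule)))
    expect_equal(got$support, want$support,
                 info = paste("seed", seed, format_rule(rule)))
  }
})

test_that("rules file TSV round-trips bit-exactly", {
  rules <- printed_rule_fixtures()
  rules$rules[[1]]$support <- 7L
  rules$rules[[1]]$body_count <- 13L
  rules$rules[[1]]$confidence <- 7 / 13
  path <- withr::local_tempfile()
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(length(back), length(rules))
  for (i in seq_along(rules$rules)) {
    expect_identical(format_rule(back$rules[[i]]), format_rule(rules$rules[[i]]))
    expect_identical(back$rules[[i]]$confidence, rules$rules[[i]]$confidence)
    expect_identical(back$rules[[i]]$support, rules$rules[[i]]$support)
  }
  # writing what was read reproduces the file byte for byte
  path2 <- withr::local_tempfile()
  write_rules(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("learning recovers a planted always-true motif and is deterministic", {
  sim <- generate_kg(synthetic_config(seed = 3))
  cfg <- learner_config(iterations = 250L, seed = 8L)
  rules <- learn_rules(sim$kg, cfg)
  texts <- vapply(rules$rules, format_rule, character(1))
  planted <- sim$truth$rules[[1]]$rule
  expect_true(planted %in% texts)
  conf <- rules$rules[[which(texts == planted)]]$confidence
  expect_equal(conf, 1.0)
  # determinism
  rules_again <- learn_rules(sim$kg, cfg)
  expect_identical(vapply(rules_again$rules, format_rule, character(1)), texts)
  # zero budget
  expect_length(learn_rules(sim$kg, learner_config(iterations = 0L, seed = 8L)),
                0L)
})

test_that("the rule set grows monotonically with the iteration budget", {
  sim <- generate_kg(synthetic_config(seed = 3))
  short <- learn_rules(sim$kg, learner_config(iterations = 60L, seed = 2L))
  long <- learn_rules(sim$kg, learner_config(iterations = 180L, seed = 2L))
  short_texts <- vapply(short$rules, format_rule, character(1))
  long_texts <- vapply(long$rules, format_rule, character(1))
  expect_true(all(short_texts %in% long_texts))
  expect_gte(length(long_texts), length(short_texts))
  # confidence bounds hold for everything learnt
  confs <- vapply(long$rules, function(r) r$confidence, numeric(1))
  expect_true(all(confs >= 0 & confs <= 1))
})
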