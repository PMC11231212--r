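# Independent brute-force oracles used by the property suites. These scan a
# plain edge data.frame directly and share no traversal code with the
# package internals they check.

random_kg <- function(seed, n_nodes = 15L, n_edges = 35L, n_rels = 4L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  types <- sample(kg_node_types(), n_nodes, replace = TRUE)
  rels <- paste0("r", seq_len(n_rels))
  h <- sample(ids, n_edges, replace = TRUE)
  t <- sample(ids, n_edges, replace = TRUE)
  r <- sample(rels, n_edges, replace = TRUE)
  ok <- h != t
  tr <- unique(data.frame(head = h[ok], relation = r[ok], tail = t[ok],
                          stringsAsFactors = FALSE))
  kgraph(tr, data.frame(id = ids, node_type = types,
                        stringsAsFactors = FALSE))
}

path_key <- function(nodes, rels, fwd) {
  paste(paste(nodes, collapse = "|"), paste(rels, collapse = "|"),
        paste(as.integer(fwd), collapse = ""), sep = "||")
}

# every simple path of 1..max_edges edges between source and target,
# traversing edges in either direction, by naive edge-table scanning
oracle_paths <- function(edges, source, target, max_edges) {
  out <- character(0)
  rec <- function(node, nodes, rels, fwds) {
    if (length(rels) >= max_edges) return(invisible(NULL))
    for (i in seq_len(nrow(edges))) {
      if (edges$head[i] == node && !(edges$tail[i] %in% nodes)) {
        nxt <- edges$tail[i]; fw <- TRUE
      } else if (edges$tail[i] == node && !(edges$head[i] %in% nodes)) {
        nxt <- edges$head[i]; fw <- FALSE
      } else {
        next
      }
      r2 <- c(rels, edges$relation[i]); f2 <- c(fwds, fw)
      if (nxt == target) {
        out <<- c(out, path_key(c(nodes, nxt), r2, f2))
      } else {
        rec(nxt, c(nodes, nxt), r2, f2)
      }
    }
  }
  rec(source, source, character(0), logical(0))
  sort(unique(out))
}

# all (X, Y) endpoint pairs with >= 1 body grounding, enumerating variable
# assignments atom by atom (nodes may repeat along a grounding)
oracle_rule_pairs <- function(edges, rule) {
  pairs <- character(0)
  n <- length(rule$relations)
  rec <- function(i, x0, cur) {
    if (i > n) {
      pairs <<- c(pairs, paste(x0, cur))
      return(invisible(NULL))
    }
    for (j in seq_len(nrow(edges))) {
      if (edges$relation[j] != rule$relations[i]) next
      from <- if (rule$forward[i]) edges$head[j] else edges$tail[j]
      to <- if (rule$forward[i]) edges$tail[j] else edges$head[j]
      if (from != cur) next
      rec(i + 1L, x0, to)
    }
  }
  starts <- unique(if (rule$forward[1]) {
    edges$head[edges$relation == rule$relations[1]]
  } else {
    edges$tail[edges$relation == rule$relations[1]]
  })
  for (v in starts) rec(1L, v, v)
  sort(unique(pairs))
}

oracle_score <- function(edges, rule) {
  pairs <- oracle_rule_pairs(edges, rule)
  head_pairs <- paste(edges$head[edges$relation == rule$head_relation],
                      edges$tail[edges$relation == rule$head_relation])
  list(body_count = length(pairs), support = sum(pairs %in% head_pairs))
}

# all simple groundings drug -> disease of a rule body (distinct nodes)
oracle_groundings <- function(edges, rule, drug, disease) {
  out <- character(0)
  n <- length(rule$relations)
  rec <- function(i, nodes) {
    cur <- nodes[length(nodes)]
    for (j in seq_len(nrow(edges))) {
      if (edges$relation[j] != rule$relations[i]) next
      from <- if (rule$forward[i]) edges$head[j] else edges$tail[j]
      to <- if (rule$forward[i]) edges$tail[j] else edges$head[j]
      if (from != cur || to %in% nodes) next
      if (i == n) {
        if (to == disease) out <<- c(out, path_key(c(nodes, to),
                                                   rule$relations,
                                                   rule$forward))
      } else if (to != disease) {
        rec(i + 1L, c(nodes, to))
      }
    }
  }
  rec(1L, drug)
  sort(unique(out))
}

# hypergeometric upper tail P(X >= k) by direct binomial-coefficient summation
oracle_fisher_p <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

chain_keys <- function(chains) sort(vapply(chains, chain_key, character(1)))

random_rule <- function(kg, max_len = 3L) {
  rels <- kg_relations(kg)
  len <- sample.int(max_len, 1L)
  kg_rule("r1", sample(rels, len, replace = TRUE),
          sample(c(TRUE, FALSE), len, replace = TRUE))
}
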