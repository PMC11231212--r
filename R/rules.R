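# Bottom-up anytime learning of cyclic path rules, in the style of
# rule-based knowledge-base completion: sample a ground path between the
# endpoints of a known target triple, generalize it to a variable rule, and
# score the rule's confidence over the whole graph.

#' Construct a path rule
#'
#' A cyclic path rule `h(X, Y) <= b1(...), ..., bn(...)` whose body is an
#' ordered chain of relations connecting the head variable X to the head
#' variable Y. Each body atom carries an orientation: `forward = TRUE` means
#' the atom is traversed head-to-tail when walking the body from X to Y;
#' reversed atoms are written with swapped variables in the rule text.
#'
#' @param head_relation relation id of the rule head (e.g. `"treats"`).
#' @param relations character vector of body relation ids, in walk order.
#' @param forward logical vector of per-atom orientations.
#' @param support,body_count,confidence scoring fields; NA until scored.
#' @return Object of class `kg_rule`.
#' @export
kg_rule <- function(head_relation, relations, forward,
                    support = NA_integer_, body_count = NA_integer_,
                    confidence = NA_real_) {
  relations <- as.character(relations)
  forward <- as.logical(forward)
  stopifnot(length(relations) >= 1L, length(forward) == length(relations))
  structure(list(head_relation = as.character(head_relation),
                 relations = relations, forward = forward,
                 support = support, body_count = body_count,
                 confidence = confidence),
            class = "kg_rule")
}

rule_vars <- function(n_atoms) {
  # X, A, B, C, ..., Y: deterministic variable names along the body walk
  mids <- if (n_atoms > 1L) setdiff(LETTERS, c("X", "Y"))[seq_len(n_atoms - 1L)] else character(0)
  c("X", mids, "Y")
}

#' Render a rule in its canonical text form
#'
#' For example `treats(X,Y) <= binds(X,A), activates(B,A), in_trial_for(B,Y)`
#' where `activates(B,A)` is a reversed atom (walked A to B against the edge
#' direction) written with swapped variables.
#'
#' @param rule a [kg_rule()].
#' @return Character scalar.
#' @export
format_rule <- function(rule) {
  v <- rule_vars(length(rule$relations))
  atoms <- vapply(seq_along(rule$relations), function(i) {
    a <- v[i]; b <- v[i + 1L]
    if (rule$forward[i]) sprintf("%s(%s,%s)", rule$relations[i], a, b)
    else sprintf("%s(%s,%s)", rule$relations[i], b, a)
  }, character(1))
  sprintf("%s(X,Y) <= %s", rule$head_relation, paste(atoms, collapse = ", "))
}

#' @export
format.kg_rule <- function(x, ...) format_rule(x)

#' @export
print.kg_rule <- function(x, ...) {
  cat(format_rule(x))
  if (!is.na(x$confidence)) {
    cat(sprintf("  [support %d / body %d, conf %.4g]",
                x$support, x$body_count, x$confidence))
  }
  cat("\n")
  invisible(x)
}

#' Parse a rule from its canonical text form
#' @param text rule text as produced by [format_rule()].
#' @return A [kg_rule()] with scoring fields unset.
#' @export
parse_rule <- function(text) {
  text <- trimws(text)
  halves <- strsplit(text, "<=", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("rule text must contain '<=': ", text)
  m <- regmatches(halves[1], regexec("^\\s*([^()\\s]+)\\(([A-Z]+),([A-Z]+)\\)\\s*$", halves[1], perl = TRUE))[[1]]
  if (length(m) != 4L || m[3] != "X" || m[4] != "Y") {
    stop("rule head must be of the form rel(X,Y): ", halves[1])
  }
  head_relation <- m[2]
  atom_texts <- strsplit(halves[2], "\\)\\s*,")[[1]]
  atom_texts <- trimws(gsub(")", "", atom_texts, fixed = TRUE))
  rels <- character(0); fwd <- logical(0)
  current <- "X"
  n <- length(atom_texts)
  v <- rule_vars(n)
  for (i in seq_len(n)) {
    am <- regmatches(atom_texts[i], regexec("^([^()\\s]+)\\(([A-Z]+),([A-Z]+)$", atom_texts[i], perl = TRUE))[[1]]
    if (length(am) != 4L) stop("malformed body atom: ", atom_texts[i])
    rel <- am[2]; a <- am[3]; b <- am[4]
    nxt <- v[i + 1L]
    if (a == current && b == nxt) {
      fwd <- c(fwd, TRUE)
    } else if (b == current && a == nxt) {
      fwd <- c(fwd, FALSE)
    } else {
      stop("body atom does not chain variables ", current, " -> ", nxt, ": ",
           atom_texts[i])
    }
    rels <- c(rels, rel)
    current <- nxt
  }
  kg_rule(head_relation, rels, fwd)
}

#' Construct a rule set
#'
#' @param rules list of [kg_rule()] (duplicates on canonical text collapsed;
#'   first occurrence wins).
#' @param provenance optional list recording the learner configuration.
#' @return Object of class `rule_set`.
#' @export
rule_set <- function(rules = list(), provenance = NULL) {
  texts <- vapply(rules, format_rule, character(1))
  keep <- !duplicated(texts)
  structure(list(rules = rules[keep], provenance = provenance),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rule(s)\n", length(x$rules)))
  for (r in x$rules) print(r)
  invisible(x)
}

#' @export
length.rule_set <- function(x) length(x$rules)

#' Write a rule set as TSV
#'
#' Columns `support`, `body_count`, `confidence`, `rule`; confidence printed
#' with 17 significant digits so that read/write round-trips bit-exactly.
#'
#' @param rules a [rule_set()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(rules$rules, function(r) {
    conf <- if (is.na(r$confidence)) "NA" else sprintf("%.17g", r$confidence)
    sprintf("%s\t%s\t%s\t%s",
            ifelse(is.na(r$support), "NA", as.character(r$support)),
            ifelse(is.na(r$body_count), "NA", as.character(r$body_count)),
            conf, format_rule(r))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rule set written by [write_rules()]
#' @param path rules TSV file.
#' @return A [rule_set()].
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rules <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) stop("malformed rules row: ", l)
    r <- parse_rule(f[4])
    r$support <- if (f[1] == "NA") NA_integer_ else as.integer(f[1])
    r$body_count <- if (f[2] == "NA") NA_integer_ else as.integer(f[2])
    r$confidence <- if (f[3] == "NA") NA_real_ else as.numeric(f[3])
    r
  })
  rule_set(rules)
}

#' Learner configuration
#'
#' The learning loop runs in spans: either a fixed number of sampling
#' iterations (deterministic given `seed`; used throughout the test suite)
#' or a wall-clock budget in seconds (the anytime production mode, spans of
#' length `time_span`).
#'
#' @param iterations number of sample-generalize-score iterations; NULL to
#'   use the wall-clock budget instead.
#' @param time_span seconds per learning span (wall-clock mode).
#' @param total_budget total seconds (wall-clock mode).
#' @param max_body_len maximum body atoms per rule.
#' @param seed integer RNG seed.
#' @param smoothing non-negative constant added to the confidence
#'   denominator.
#' @param min_support minimum support for a rule to be retained.
#' @param target_relation head relation learnt (default `"treats"`).
#' @param walk_attempts random-walk restarts per sampled target triple.
#' @return Object of class `learner_config`.
#' @export
learner_config <- function(iterations = 200L, time_span = 10, total_budget = 30,
                           max_body_len = 3L, seed = 1L, smoothing = 0,
                           min_support = 2L, target_relation = "treats",
                           walk_attempts = 10L) {
  stopifnot(max_body_len >= 1L, smoothing >= 0, time_span > 0)
  structure(list(iterations = if (is.null(iterations)) NULL else as.integer(iterations),
                 time_span = time_span, total_budget = total_budget,
                 max_body_len = as.integer(max_body_len), seed = as.integer(seed),
                 smoothing = smoothing, min_support = as.integer(min_support),
                 target_relation = target_relation,
                 walk_attempts = as.integer(walk_attempts)),
            class = "learner_config")
}

#' Sample a ground path between the endpoints of a target-relation triple
#'
#' Uniformly samples one triple of the target relation, then random-walks
#' from its head towards its tail (each step follows any triple in either
#' direction, never revisiting a node and never using the sampled triple
#' itself). Consumes the session RNG; seed with `set.seed()` for
#' reproducibility.
#'
#' @param kg a `kgraph`.
#' @param target_relation relation whose facts the walk tries to explain.
#' @param max_edges maximum walk length in edges.
#' @param walk_attempts number of restarts before giving up on the pair.
#' @return An [evidence_chain()] ground path, or NULL when no path was found
#'   within the attempt budget.
#' @export
sample_ground_path <- function(kg, target_relation = "treats", max_edges = 3L,
                               walk_attempts = 10L) {
  tr <- kg$triples
  targets <- tr[tr$relation == target_relation]
  if (nrow(targets) == 0L) {
    stop("no triples with target relation '", target_relation, "'")
  }
  pick <- targets[sample.int(nrow(targets), 1L)]
  h <- pick$head; t <- pick$tail
  for (attempt in seq_len(walk_attempts)) {
    nodes <- h; rels <- character(0); fwd <- logical(0)
    current <- h
    repeat {
      if (length(rels) >= max_edges) break
      nb <- kg_neighbors(kg, current)
      # never walk the sampled head triple itself, in either direction
      self_edge <- nb$relation == target_relation &
        ((current == h & nb$neighbor == t & nb$forward) |
           (current == t & nb$neighbor == h & !nb$forward))
      nb <- nb[!self_edge & !(nb$neighbor %in% nodes)]
      if (nrow(nb) == 0L) break
      i <- sample.int(nrow(nb), 1L)
      nxt <- nb$neighbor[i]
      rels <- c(rels, nb$relation[i]); fwd <- c(fwd, nb$forward[i])
      nodes <- c(nodes, nxt)
      if (identical(nxt, t)) {
        return(evidence_chain(nodes, rels, fwd, origin = "extracted"))
      }
      current <- nxt
    }
  }
  NULL
}

#' Generalize a ground path into a path rule
#'
#' Every concrete node is replaced by a fresh variable; the relation and
#' orientation sequence is preserved, so two ground paths with the same
#' relation/orientation sequence generalize to the identical rule.
#'
#' @param ground_path an [evidence_chain()] between the head triple's
#'   endpoints.
#' @param head_relation the head relation of the resulting rule.
#' @return A [kg_rule()] with scoring fields unset.
#' @export
generalize <- function(ground_path, head_relation) {
  kg_rule(head_relation, ground_path$relations, ground_path$forward)
}

oriented_pairs <- function(tr, relation, forward) {
  rel <- relation
  hit <- tr[tr$relation == rel]
  if (forward) data.table::data.table(from = hit$head, to = hit$tail)
  else data.table::data.table(from = hit$tail, to = hit$head)
}

# distinct (X, Y) endpoint pairs admitting >= 1 body grounding, by
# relational joins over the triple table (variable assignments are
# unrestricted: nodes may repeat along a grounding)
rule_body_pairs <- function(tr, rule) {
  pairs <- unique(oriented_pairs(tr, rule$relations[1], rule$forward[1]))
  data.table::setnames(pairs, c("x", "cur"))
  for (i in seq_along(rule$relations)[-1]) {
    if (nrow(pairs) == 0L) break
    step <- oriented_pairs(tr, rule$relations[i], rule$forward[i])
    pairs <- merge(pairs, step, by.x = "cur", by.y = "from",
                   allow.cartesian = TRUE)[, c("x", "to")]
    data.table::setnames(pairs, c("x", "cur"))
    pairs <- unique(pairs)
  }
  data.table::setnames(pairs, c("x", "y"))
  pairs
}

#' Score a rule's support, body count and confidence over a graph
#'
#' The body is evaluated by relational joins: `body_count` is the number of
#' distinct (X, Y) endpoint pairs admitting at least one body grounding
#' (variable assignments are unrestricted; nodes may repeat), and `support`
#' the number of those pairs for which the head triple exists. Confidence is
#' `support / (body_count + smoothing)`. Counting endpoint pairs rather than
#' raw groundings keeps confidence in [0, 1] and immune to multiplicity
#' inflation from parallel intermediate routes.
#'
#' @param kg a `kgraph`.
#' @param rule a [kg_rule()].
#' @param smoothing non-negative constant added to the denominator.
#' @return The rule with `support`, `body_count`, `confidence` filled in.
#'   A rule whose body has no grounding gets `body_count = 0` and
#'   `confidence = NA` (unscorable).
#' @export
score_rule <- function(kg, rule, smoothing = 0) {
  pairs <- rule_body_pairs(kg$triples, rule)
  rule$body_count <- nrow(pairs)
  if (rule$body_count == 0L) {
    rule$support <- 0L
    rule$confidence <- NA_real_
    return(rule)
  }
  heads <- unique(oriented_pairs(kg$triples, rule$head_relation, TRUE))
  data.table::setnames(heads, c("x", "y"))
  rule$support <- nrow(merge(pairs, heads, by = c("x", "y")))
  rule$confidence <- rule$support / (rule$body_count + smoothing)
  rule
}

#' Learn path rules bottom-up with an anytime loop
#'
#' Repeats sample-generalize-score for the configured budget. With an
#' iteration budget the run is fully deterministic given the seed, and a
#' longer budget yields a superset of the rules found with a shorter one
#' (anytime monotonicity). Rules are kept when scorable with
#' `support >= min_support`.
#'
#' @param kg a `kgraph`.
#' @param config a [learner_config()].
#' @return A [rule_set()]; rules unique on their canonical text.
#' @export
learn_rules <- function(kg, config = learner_config()) {
  tr <- kg$triples
  if (!any(tr$relation == config$target_relation)) {
    stop("no triples with target relation '", config$target_relation, "'")
  }
  set.seed(config$seed)
  seen <- new.env(parent = emptyenv())
  kept <- list()
  consider <- function() {
    gp <- sample_ground_path(kg, config$target_relation, config$max_body_len,
                             config$walk_attempts)
    if (is.null(gp)) return(invisible(NULL))
    rule <- generalize(gp, config$target_relation)
    key <- format_rule(rule)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    rule <- score_rule(kg, rule, config$smoothing)
    if (!is.na(rule$confidence) && rule$support >= config$min_support) {
      kept[[length(kept) + 1L]] <<- rule
    }
    invisible(NULL)
  }
  if (!is.null(config$iterations)) {
    for (it in seq_len(config$iterations)) consider()
  } else {
    t0 <- Sys.time()
    while (as.numeric(Sys.time() - t0, units = "secs") < config$total_budget) {
      span0 <- Sys.time()
      while (as.numeric(Sys.time() - span0, units = "secs") < config$time_span &&
             as.numeric(Sys.time() - t0, units = "secs") < config$total_budget) {
        consider()
      }
    }
  }
  rule_set(kept, provenance = unclass(config))
}
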