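# Applying learnt rules to a query and ranking candidate treatments by
# lexicographic comparison of their rule-confidence vectors.

#' Treatment query
#'
#' Fixes one end of a relation and asks for the other: the default drug-
#' repositioning query fixes the disease (tail of `treats`) and predicts
#' compounds (head side).
#'
#' @param relation relation id to complete (default `"treats"`).
#' @param fixed_entity the known entity (usually the disease).
#' @param predict_side which side to predict: `"head"` or `"tail"`.
#' @return Object of class `kg_query`.
#' @export
kg_query <- function(relation = "treats", fixed_entity,
                     predict_side = c("head", "tail")) {
  predict_side <- match.arg(predict_side)
  structure(list(relation = relation, fixed_entity = fixed_entity,
                 predict_side = predict_side), class = "kg_query")
}

rule_endpoint_pairs <- function(kg, rule) {
  rule_body_pairs(kg$triples, rule)
}

#' Apply a rule set to a query
#'
#' A candidate entity is proposed whenever at least one rule body has a
#' grounding connecting it to the query's fixed entity; each candidate
#' carries the confidences of all suggesting rules, sorted descending.
#' Edges previously removed from the graph (held-out treatments) are not
#' re-added, so held-out drugs can only be proposed through rule bodies.
#'
#' @param kg a `kgraph`.
#' @param rules a [rule_set()]; rules whose head relation differs from the
#'   query relation are ignored.
#' @param query a [kg_query()].
#' @return data.table with one row per candidate: `candidate`,
#'   `rule_confidences` (list column, descending), `max_confidence`,
#'   `n_rules`. Unranked. Empty (with a warning) for an empty rule set.
#' @export
apply_rules <- function(kg, rules, query) {
  empty <- data.table::data.table(candidate = character(),
                                  rule_confidences = list(),
                                  max_confidence = numeric(),
                                  n_rules = integer())
  usable <- Filter(function(r) r$head_relation == query$relation &&
                     !is.na(r$confidence), rules$rules)
  if (length(usable) == 0L) {
    warning("no scored rules with head relation '", query$relation, "'")
    return(empty)
  }
  per_cand <- new.env(parent = emptyenv())
  for (r in usable) {
    pairs <- rule_endpoint_pairs(kg, r)
    cands <- if (query$predict_side == "head") {
      pairs$x[pairs$y == query$fixed_entity]
    } else {
      pairs$y[pairs$x == query$fixed_entity]
    }
    for (cand in unique(cands)) {
      per_cand[[cand]] <- c(per_cand[[cand]], r$confidence)
    }
  }
  cand_ids <- ls(per_cand)
  if (length(cand_ids) == 0L) return(empty)
  confs <- lapply(cand_ids, function(id) sort(per_cand[[id]], decreasing = TRUE))
  data.table::data.table(
    candidate = cand_ids,
    rule_confidences = confs,
    max_confidence = vapply(confs, `[`, numeric(1), 1L),
    n_rules = lengths(confs)
  )
}

#' Rank candidates by lexicographic confidence comparison
#'
#' Candidates are ordered by the maximum confidence of their suggesting
#' rules; ties are broken by the second-best rule, and so on. A candidate
#' with no further rule loses to one that still has some. Full ties are
#' broken by ascending candidate id so the ranking is a deterministic total
#' order.
#'
#' @param predictions data.table from [apply_rules()].
#' @return The same table ordered, with a `rank` column (1..N) added.
#' @export
rank_candidates <- function(predictions) {
  n <- nrow(predictions)
  if (n == 0L) {
    out <- data.table::copy(predictions)
    out[, rank := integer(0)]
    return(out)
  }
  maxlen <- max(lengths(predictions$rule_confidences))
  pad <- t(vapply(predictions$rule_confidences, function(v) {
    c(v, rep(-Inf, maxlen - length(v)))
  }, numeric(maxlen)))
  if (maxlen == 1L) pad <- matrix(pad, ncol = 1L)
  ord_args <- c(lapply(seq_len(maxlen), function(j) -pad[, j]),
                list(predictions$candidate))
  ord <- do.call(order, ord_args)
  out <- predictions[ord]
  out[, rank := seq_len(n)]
  out
}

#' Recall of held-out treatment edges among the top-k candidates
#'
#' After removing known treatment edges and re-predicting, measures the
#' fraction of the held-out drugs recovered within the top k ranks.
#'
#' @param ranked ranked predictions from [rank_candidates()].
#' @param removed data.table of removed triples (from
#'   [remove_target_edges()]); drug ids are taken from the `head` column.
#' @param k rank cutoff (>= 1).
#' @return List with `recall` (fraction in [0, 1]) and `hits` (data.table:
#'   drug, found, rank).
#' @export
evaluate_holdout_recall <- function(ranked, removed, k = 100L) {
  if (is.null(removed) || nrow(removed) == 0L) {
    stop("removed set is empty; nothing to evaluate")
  }
  stopifnot(k >= 1L)
  drugs <- sort(unique(removed$head))
  topk <- ranked$candidate[ranked$rank <= k]
  found <- drugs %in% topk
  ranks <- ranked$rank[match(drugs, ranked$candidate)]
  list(recall = mean(found),
       hits = data.table::data.table(drug = drugs, found = found, rank = ranks))
}

#' Write ranked predictions as TSV
#' @param ranked output of [rank_candidates()].
#' @param path destination (`rank`, `candidate`, `max_confidence`,
#'   `n_rules`).
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(ranked, path) {
  out <- ranked[, c("rank", "candidate", "max_confidence", "n_rules")]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
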