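# Evidence chains: grounded compound-to-disease paths with per-edge
# orientation and provenance.

#' Construct an evidence chain
#'
#' An evidence chain is an ordered path of entities connected by graph
#' triples, each traversed either forward (head-to-tail) or reversed. Chains
#' explain why a compound may treat a disease: the first node is typically a
#' Compound and the last a Disease.
#'
#' @param nodes ordered character vector of entity ids (length n + 1).
#' @param relations character vector of relation ids (length n).
#' @param forward logical vector (length n); TRUE when the edge is traversed
#'   from triple head to triple tail.
#' @param origin `"extracted"` (grounded from a learnt rule or enumeration)
#'   or `"deduced"` (built by the deductive path builder).
#' @param source_rules character vector of rule texts that produced the
#'   chain (may be empty).
#' @return Object of class `evidence_chain`.
#' @export
evidence_chain <- function(nodes, relations, forward,
                           origin = c("extracted", "deduced"),
                           source_rules = character(0)) {
  origin <- match.arg(origin)
  nodes <- as.character(nodes)
  relations <- as.character(relations)
  forward <- as.logical(forward)
  if (length(nodes) != length(relations) + 1L) {
    stop("chain must have one more node than edges")
  }
  if (length(forward) != length(relations)) {
    stop("one orientation flag per edge required")
  }
  structure(list(nodes = nodes, relations = relations, forward = forward,
                 origin = origin, source_rules = as.character(source_rules)),
            class = "evidence_chain")
}

#' @export
format.evidence_chain <- function(x, ...) {
  n <- length(x$relations)
  parts <- x$nodes[1L]
  for (i in seq_len(n)) {
    arrow <- if (x$forward[i]) {
      paste0("-", x$relations[i], "->")
    } else {
      paste0("<-", x$relations[i], "-")
    }
    parts <- paste(parts, arrow, x$nodes[i + 1L])
  }
  parts
}

#' @export
print.evidence_chain <- function(x, ...) {
  cat(format(x), sprintf("[%s]\n", x$origin))
  invisible(x)
}

#' Identity key of an evidence chain
#'
#' Chains are identified by their node sequence plus relation/orientation
#' sequence; provenance (origin, source rules) is not part of identity.
#'
#' @param chain an [evidence_chain()].
#' @return Character scalar usable as a dedup key.
#' @export
chain_key <- function(chain) {
  paste(paste(chain$nodes, collapse = "|"),
        paste(chain$relations, collapse = "|"),
        paste(as.integer(chain$forward), collapse = ""), sep = "||")
}

chain_node_key <- function(chain) paste(chain$nodes, collapse = "|")

#' De-duplicate a list of chains on their identity key
#'
#' Provenance from duplicates is merged: source rules are unioned and the
#' first occurrence's origin kept.
#'
#' @param chains list of [evidence_chain()].
#' @return List of unique chains, input order of first occurrence preserved.
#' @export
dedup_chains <- function(chains) {
  if (length(chains) == 0L) return(list())
  keys <- vapply(chains, chain_key, character(1))
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(chains)) {
    k <- keys[i]
    if (is.null(seen[[k]])) {
      seen[[k]] <- length(out) + 1L
      out[[length(out) + 1L]] <- chains[[i]]
    } else {
      j <- seen[[k]]
      out[[j]]$source_rules <- union(out[[j]]$source_rules,
                                     chains[[i]]$source_rules)
    }
  }
  out
}

#' Check that every edge of a chain exists in the graph
#' @param kg a `kgraph`.
#' @param chain an [evidence_chain()].
#' @return Logical scalar.
#' @export
chain_in_kg <- function(kg, chain) {
  for (i in seq_along(chain$relations)) {
    a <- chain$nodes[i]; b <- chain$nodes[i + 1L]
    h <- if (chain$forward[i]) a else b
    t <- if (chain$forward[i]) b else a
    if (!kg_has_triple(kg, h, chain$relations[i], t)) return(FALSE)
  }
  TRUE
}

#' Write chains as JSON lines
#'
#' One JSON object per line with fields `nodes`, `relations`, `forward`,
#' `origin` and `source_rules`.
#'
#' @param chains list of [evidence_chain()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_chains <- function(chains, path) {
  lines <- vapply(chains, function(ch) {
    as.character(jsonlite::toJSON(list(
      nodes = ch$nodes, relations = ch$relations,
      forward = ch$forward, origin = ch$origin,
      source_rules = ch$source_rules)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read chains written by [write_chains()]
#' @param path JSON-lines file.
#' @return List of [evidence_chain()].
#' @export
read_chains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(l) {
    x <- jsonlite::fromJSON(l)
    evidence_chain(x$nodes, x$relations, x$forward, origin = x$origin,
                   source_rules = unlist(x$source_rules))
  })
}

#' Summarise a list of chains as a data.table
#' @param chains list of [evidence_chain()].
#' @return data.table with one row per chain: compound, disease, length,
#'   origin, rendered path and number of source rules.
#' @export
chains_summary <- function(chains) {
  data.table::data.table(
    compound = vapply(chains, function(ch) ch$nodes[1L], character(1)),
    disease = vapply(chains, function(ch) ch$nodes[length(ch$nodes)], character(1)),
    n_edges = vapply(chains, function(ch) length(ch$relations), integer(1)),
    origin = vapply(chains, function(ch) ch$origin, character(1)),
    path = vapply(chains, format, character(1)),
    n_rules = vapply(chains, function(ch) length(ch$source_rules), integer(1))
  )
}
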