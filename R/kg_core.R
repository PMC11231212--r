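# Knowledge-graph container: typed entities + directed labelled triples,
# with keyed indices for neighbour lookup in either direction.

#' Node-type vocabulary of the biomedical meta-graph
#'
#' The eight node types used throughout: Compound, Disease, Gene, Protein,
#' Pathway, Mechanism, ATC and Phenotype.
#'
#' @return Character vector of the eight admissible node types.
#' @export
kg_node_types <- function() {
  c("Compound", "Disease", "Gene", "Protein", "Pathway",
    "Mechanism", "ATC", "Phenotype")
}

#' Construct a typed knowledge graph from triples and a node-type table
#'
#' @param triples data.frame with columns `head`, `relation`, `tail`
#'   (character). Duplicate rows are collapsed.
#' @param node_types data.frame with columns `id`, `node_type` and optionally
#'   `label`; must cover every id appearing in `triples`.
#' @param check validate node types against [kg_node_types()] (default TRUE).
#' @return An object of class `kgraph` with elements `entities` (data.table:
#'   id, node_type, label) and `triples` (data.table: head, relation, tail),
#'   indexed on both endpoints.
#' @export
kgraph <- function(triples, node_types, check = TRUE) {
  tr <- data.table::as.data.table(triples)[, c("head", "relation", "tail")]
  for (col in names(tr)) data.table::set(tr, j = col, value = as.character(tr[[col]]))
  ent <- data.table::as.data.table(node_types)
  if (!"label" %in% names(ent)) data.table::set(ent, j = "label", value = ent$id)
  ent <- ent[, c("id", "node_type", "label")]
  for (col in names(ent)) data.table::set(ent, j = col, value = as.character(ent[[col]]))

  if (anyDuplicated(ent$id)) stop("duplicate entity ids in node-type table")
  if (any(!nzchar(ent$id))) stop("empty entity id in node-type table")
  if (check) {
    bad <- setdiff(unique(ent$node_type), kg_node_types())
    if (length(bad)) stop("unknown node types: ", paste(bad, collapse = ", "))
  }
  tr <- unique(tr)
  ids <- unique(c(tr$head, tr$tail))
  missing_type <- setdiff(ids, ent$id)
  if (length(missing_type)) {
    stop("ids without a node type: ", paste(missing_type, collapse = ", "))
  }
  data.table::setkeyv(tr, c("head", "relation"))
  data.table::setindexv(tr, c("tail", "relation"))
  data.table::setkeyv(ent, "id")
  structure(list(entities = ent, triples = tr), class = "kgraph")
}

#' @export
print.kgraph <- function(x, ...) {
  cat(sprintf("<kgraph> %d entities (%d types), %d triples (%d relations)\n",
              nrow(x$entities), length(unique(x$entities$node_type)),
              nrow(x$triples), length(unique(x$triples$relation))))
  invisible(x)
}

#' Number of triples / entities in a knowledge graph
#' @param kg a `kgraph`.
#' @return Integer count.
#' @export
kg_n_triples <- function(kg) nrow(kg$triples)

#' @rdname kg_n_triples
#' @export
kg_n_entities <- function(kg) nrow(kg$entities)

#' Relation names present in a graph
#' @param kg a `kgraph`.
#' @return Character vector of distinct relation identifiers.
#' @export
kg_relations <- function(kg) sort(unique(kg$triples$relation))

#' Node type of one or more entities
#' @param kg a `kgraph`.
#' @param ids entity ids.
#' @return Character vector of node types (NA for unregistered ids).
#' @export
kg_node_type <- function(kg, ids) {
  kg$entities$node_type[match(ids, kg$entities$id)]
}

kg_has_entity <- function(kg, id) id %in% kg$entities$id

#' Does the graph contain a given triple?
#' @param kg a `kgraph`.
#' @param head,relation,tail components of the triple.
#' @return Logical scalar.
#' @export
kg_has_triple <- function(kg, head, relation, tail) {
  h <- head; r <- relation; t <- tail
  tr <- kg$triples
  nrow(tr[tr$head == h & tr$relation == r & tr$tail == t]) > 0L
}

#' Neighbours of a node, optionally restricted by relation and direction
#'
#' @param kg a `kgraph`.
#' @param node entity id.
#' @param relation optional relation id; NULL means any relation.
#' @param direction `"out"` (node is head), `"in"` (node is tail) or
#'   `"both"`.
#' @return data.table with columns `neighbor`, `relation`, `forward`
#'   (TRUE when the underlying triple is traversed head-to-tail).
#' @export
kg_neighbors <- function(kg, node, relation = NULL,
                         direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  rel <- relation
  tr <- kg$triples
  out <- NULL
  if (direction %in% c("out", "both")) {
    hit <- tr[tr$head == node]
    if (!is.null(rel)) hit <- hit[hit$relation == rel]
    out <- data.table::data.table(neighbor = hit$tail, relation = hit$relation,
                                  forward = rep(TRUE, nrow(hit)))
  }
  inn <- NULL
  if (direction %in% c("in", "both")) {
    hit <- tr[tr$tail == node]
    if (!is.null(rel)) hit <- hit[hit$relation == rel]
    inn <- data.table::data.table(neighbor = hit$head, relation = hit$relation,
                                  forward = rep(FALSE, nrow(hit)))
  }
  res <- data.table::rbindlist(list(out, inn))
  if (nrow(res) == 0L) {
    res <- data.table::data.table(neighbor = character(), relation = character(),
                                  forward = logical())
  }
  res
}

#' Load a knowledge graph from triples and node-type TSV files
#'
#' The triples file is tab-separated `head<TAB>relation<TAB>tail` with no
#' header (the layout consumed by rule-based KBC learners). The node-type
#' file is tab-separated with a header line and columns `id`, `node_type`
#' and optionally `label`, covering every id in the triples file.
#'
#' @param path triples TSV path.
#' @param node_type_path node-type TSV path.
#' @return A [kgraph()]. Duplicate triple rows are collapsed; the number of
#'   collapsed duplicates is reported with a message.
#' @export
load_triples <- function(path, node_type_path) {
  if (!file.exists(path)) stop("triples file not found: ", path)
  if (!file.exists(node_type_path)) stop("node-type file not found: ", node_type_path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    tr <- data.table::data.table(head = character(), relation = character(),
                                 tail = character())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 3L)) {
      bad <- which(nfield != 3L)[1L]
      stop(sprintf("malformed triples row at line %d: expected 3 tab-separated fields, got %d",
                   bad, nfield[bad]))
    }
    m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    tr <- data.table::data.table(head = m[, 1L], relation = m[, 2L], tail = m[, 3L])
  }
  ndup <- nrow(tr) - nrow(unique(tr))
  if (ndup > 0L) message(sprintf("collapsed %d duplicate triple row(s)", ndup))
  nt <- data.table::fread(node_type_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("id", "node_type") %in% names(nt))) {
    stop("node-type file must have header columns 'id' and 'node_type'")
  }
  ids <- unique(c(tr$head, tr$tail))
  untyped <- setdiff(ids, nt$id)
  if (length(untyped)) {
    stop("ids without a node type: ", paste(untyped, collapse = ", "))
  }
  if (nrow(tr) == 0L) {
    nt <- nt[0L]
  }
  kgraph(tr, nt)
}

#' Write a knowledge graph to triples and node-type TSV files
#' @param kg a `kgraph`.
#' @param path triples TSV destination (headerless).
#' @param node_type_path node-type TSV destination (with header).
#' @return Invisibly, `kg`.
#' @export
write_triples <- function(kg, path, node_type_path) {
  data.table::fwrite(kg$triples, path, sep = "\t", col.names = FALSE)
  data.table::fwrite(kg$entities, node_type_path, sep = "\t", col.names = TRUE)
  invisible(kg)
}

#' Remove all edges of one relation incident to a disease
#'
#' Known treatment links between a disease and its approved drugs are removed
#' from the graph before rule learning, so that recovery of those treatments
#' can serve as held-out validation.
#'
#' @param kg a `kgraph`.
#' @param disease entity id of the disease.
#' @param relation relation to strip (default `"treats"`).
#' @return List with `kg` (new graph without the edges; input unmodified) and
#'   `removed` (data.table of the removed triples).
#' @export
remove_target_edges <- function(kg, disease, relation = "treats") {
  if (!kg_has_entity(kg, disease)) stop("unknown entity id: ", disease)
  tr <- kg$triples
  drop <- tr$relation == relation & (tr$head == disease | tr$tail == disease)
  removed <- data.table::copy(tr[drop])
  kept <- data.table::copy(tr[!drop])
  list(kg = kgraph(kept, kg$entities, check = FALSE), removed = removed)
}

#' Path-length policy for baseline path enumeration
#'
#' Chain length is measured in edges; every chain printed in the worked
#' examples has three edges, so `max_edges` defaults to 3.
#'
#' @param max_edges maximum number of edges per path (>= 1).
#' @param simple_paths_only forbid repeated nodes (default TRUE).
#' @return An object of class `path_policy`.
#' @export
path_policy <- function(max_edges = 3L, simple_paths_only = TRUE) {
  max_edges <- as.integer(max_edges)
  stopifnot(length(max_edges) == 1L, max_edges >= 1L,
            is.logical(simple_paths_only))
  structure(list(max_edges = max_edges, simple_paths_only = simple_paths_only),
            class = "path_policy")
}

#' Enumerate all simple paths between two entities
#'
#' Exhaustive baseline enumeration: every simple path of 1..`max_edges` edges
#' from `source` to `target`, where each step traverses a graph triple in
#' either direction. This is the unfiltered path space a rule-free search
#' would present to a reviewer.
#'
#' @param kg a `kgraph`.
#' @param source,target registered entity ids, `source != target`.
#' @param policy a [path_policy()].
#' @return List of [evidence_chain()] objects (possibly empty), de-duplicated
#'   on (node sequence, relation + orientation sequence).
#' @export
enumerate_paths <- function(kg, source, target, policy = path_policy()) {
  if (!kg_has_entity(kg, source)) stop("unknown entity id: ", source)
  if (!kg_has_entity(kg, target)) stop("unknown entity id: ", target)
  if (identical(source, target)) stop("source and target must differ")
  found <- list()
  walk <- function(node, nodes, rels, fwd) {
    if (length(rels) >= policy$max_edges) return(invisible(NULL))
    nb <- kg_neighbors(kg, node)
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$neighbor[i]
      if (policy$simple_paths_only && nxt %in% nodes) next
      rels2 <- c(rels, nb$relation[i]); fwd2 <- c(fwd, nb$forward[i])
      if (identical(nxt, target)) {
        # a simple path can only touch the target once, so stop this branch
        found[[length(found) + 1L]] <<- evidence_chain(
          nodes = c(nodes, nxt), relations = rels2, forward = fwd2,
          origin = "extracted")
      } else {
        walk(nxt, c(nodes, nxt), rels2, fwd2)
      }
    }
  }
  walk(source, source, character(0), logical(0))
  dedup_chains(found)
}
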