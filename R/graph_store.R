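#' Normalize an entity name for exact-match lookup
#'
#' Entity linking is deliberately exact: leading/trailing whitespace is
#' trimmed, internal whitespace runs are collapsed to one space, and the
#' result is case-folded. No stemming and no fuzzy matching are applied, so a
#' name that differs from a stored name by even one character will not
#' resolve. This mirrors the retrieval behaviour of Cypher-style exact
#' matching on a name property.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_name("  Carteolol   hydrochloride ")
normalize_name <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  casefold(x, upper = FALSE)
}

# Locale-independent character sort used everywhere an ordering must be
# reproducible across machines.
sort_c <- function(x) sort(x, method = "radix")

# Coerce an attribute cell (read as character) to its natural scalar type.
parse_attr_value <- function(x) {
  if (is.logical(x) || is.numeric(x)) return(x)
  lx <- casefold(x)
  if (lx %in% c("true", "false")) return(identical(lx, "true"))
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

format_attr_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  as.character(v)
}

#' Load a knowledge graph from node and edge tables
#'
#' The store holds entities (with a type label and scalar attributes) and
#' typed relations between them, i.e. a set of (head, relation, tail)
#' triplets enriched with (entity, attribute) pairs. A name index
#' (normalized name to entity ids) and an adjacency index are built at load
#' time.
#'
#' @param nodes data.frame with columns `id`, `name`, `etype`; any further
#'   columns are entity attributes (empty cells / NA are omitted from the
#'   entity's attribute map).
#' @param edges data.frame with columns `head_id`, `label`, `tail_id`.
#' @return An object of class `kgqa_kg`.
#' @export
#' @examples
#' nodes <- data.frame(id = c("d1", "g1"),
#'                     name = c("carteolol", "ADRB1"),
#'                     etype = c("drug", "gene"))
#' edges <- data.frame(head_id = "d1", label = "inhibits", tail_id = "g1")
#' kg <- load_kg(nodes, edges)
load_kg <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("id", "name", "etype")
  if (!all(need %in% names(nodes)))
    stop_load_error("node table must have columns id, name, etype")
  if (nrow(edges) > 0 && !all(c("head_id", "label", "tail_id") %in% names(edges)))
    stop_load_error("edge table must have columns head_id, label, tail_id")
  for (cn in need) nodes[[cn]] <- as.character(nodes[[cn]])

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0)
    stop_load_error(sprintf("duplicate node id: %s", dup[1]), id = dup[1])
  if (any(!nzchar(nodes$etype)))
    stop_load_error("every node must have a non-empty etype")

  if (nrow(edges) == 0) {
    edges <- data.frame(head_id = character(0), label = character(0),
                        tail_id = character(0), stringsAsFactors = FALSE)
  } else {
    for (cn in c("head_id", "label", "tail_id")) edges[[cn]] <- as.character(edges[[cn]])
    bad <- !(edges$head_id %in% nodes$id) | !(edges$tail_id %in% nodes$id)
    if (any(bad)) {
      i <- which(bad)[1]
      stop_load_error(sprintf(
        "edge (%s, %s, %s) references an unknown node id",
        edges$head_id[i], edges$label[i], edges$tail_id[i]))
    }
    if (any(!nzchar(edges$label)))
      stop_load_error("every edge must have a non-empty label")
  }

  attr_cols <- setdiff(names(nodes), need)
  attrs <- vector("list", nrow(nodes))
  names(attrs) <- nodes$id
  for (i in seq_len(nrow(nodes))) {
    a <- list()
    for (cn in attr_cols) {
      v <- nodes[[cn]][i]
      if (is.null(v) || length(v) == 0 || is.na(v) ||
          (is.character(v) && !nzchar(v))) next
      a[[cn]] <- parse_attr_value(v)
    }
    attrs[[i]] <- a
  }

  name_index <- split(nodes$id, normalize_name(nodes$name))

  adj <- list()
  if (nrow(edges) > 0) {
    by_head <- split(seq_len(nrow(edges)), edges$head_id)
    by_tail <- split(seq_len(nrow(edges)), edges$tail_id)
    ids <- unique(c(names(by_head), names(by_tail)))
    adj <- lapply(ids, function(id)
      sort(unique(c(by_head[[id]], by_tail[[id]]))))
    names(adj) <- ids
  }

  structure(
    list(nodes = nodes[, need], attrs = attrs, edges = edges,
         name_index = name_index, adj = adj,
         row_of = stats::setNames(seq_len(nrow(nodes)), nodes$id)),
    class = "kgqa_kg")
}

#' Read a knowledge graph from a pair of CSV files
#'
#' @param nodes_csv,edges_csv Paths to UTF-8 CSV files with header rows; the
#'   node file has columns `id,name,etype` plus attribute columns, the edge
#'   file has `head_id,label,tail_id`.
#' @return A `kgqa_kg` object.
#' @export
read_kg <- function(nodes_csv, edges_csv) {
  nodes <- utils::read.csv(nodes_csv, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  edges <- utils::read.csv(edges_csv, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  load_kg(nodes, edges)
}

#' Write a knowledge graph to node/edge CSV files
#'
#' Inverse of [read_kg()]: attribute maps are spread into columns (empty cell
#' where an entity lacks the attribute). Loading the written files
#' reconstructs an isomorphic graph.
#'
#' @param kg A `kgqa_kg`.
#' @param nodes_csv,edges_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_kg <- function(kg, nodes_csv, edges_csv) {
  keys <- sort_c(unique(unlist(lapply(kg$attrs, names))))
  out <- kg$nodes
  for (k in keys) {
    out[[k]] <- vapply(kg$attrs[out$id], function(a) {
      if (is.null(a[[k]])) "" else format_attr_value(a[[k]])
    }, character(1))
  }
  utils::write.csv(out, nodes_csv, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(kg$edges, edges_csv, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(nodes_csv, edges_csv))
}

#' @export
print.kgqa_kg <- function(x, ...) {
  cat(sprintf("<kgqa knowledge graph: %d entities (%d types), %d relations (%d labels)>\n",
              nrow(x$nodes), length(unique(x$nodes$etype)),
              nrow(x$edges), length(unique(x$edges$label))))
  invisible(x)
}

entity_name <- function(kg, id) kg$nodes$name[kg$row_of[[id]]]
entity_type <- function(kg, id) kg$nodes$etype[kg$row_of[[id]]]
entity_attrs <- function(kg, id) kg$attrs[[id]]

#' Resolve an entity name to matching entities
#'
#' Exact lookup in the name index after [normalize_name()]. A query differing
#' from every stored name -- by as little as one character -- returns an empty
#' result; callers that require a match raise an entity-not-found condition.
#'
#' @param kg A `kgqa_kg`.
#' @param name Entity name to resolve (non-empty).
#' @return data.frame with columns `id`, `name`, `etype`, one row per
#'   matching entity (zero rows if none).
#' @export
resolve_entity <- function(kg, name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  ids <- kg$name_index[[normalize_name(name)]]
  kg$nodes[kg$row_of[ids], , drop = FALSE]
}

## --- relational chains -------------------------------------------------

# A relational chain is an ordered walk over entities. Steps keep both the
# traversal orientation (from/to) and the stored orientation of the
# underlying triplet (head/tail), so undirected matching does not lose the
# direction recorded in the graph.
make_chain <- function(kg, entity_ids, edge_rows) {
  n <- length(edge_rows)
  steps <- data.frame(
    from_id = character(n), from_name = character(n), from_type = character(n),
    label = character(n),
    to_id = character(n), to_name = character(n), to_type = character(n),
    head_id = character(n), head_name = character(n),
    tail_id = character(n), tail_name = character(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- kg$edges[edge_rows[i], ]
    from <- entity_ids[i]; to <- entity_ids[i + 1]
    steps$from_id[i] <- from
    steps$from_name[i] <- entity_name(kg, from)
    steps$from_type[i] <- entity_type(kg, from)
    steps$label[i] <- e$label
    steps$to_id[i] <- to
    steps$to_name[i] <- entity_name(kg, to)
    steps$to_type[i] <- entity_type(kg, to)
    steps$head_id[i] <- e$head_id
    steps$head_name[i] <- entity_name(kg, e$head_id)
    steps$tail_id[i] <- e$tail_id
    steps$tail_name[i] <- entity_name(kg, e$tail_id)
  }
  structure(list(
    entity_ids = unname(entity_ids),
    entity_names = vapply(entity_ids, function(id) entity_name(kg, id),
                          character(1), USE.NAMES = FALSE),
    entity_types = vapply(entity_ids, function(id) entity_type(kg, id),
                          character(1), USE.NAMES = FALSE),
    steps = steps), class = "kgqa_chain")
}

chain_key <- function(chain) {
  paste(c(chain$entity_ids, chain$steps$label), collapse = "\x1f")
}

sort_chains <- function(chains) {
  if (length(chains) < 2) return(chains)
  keys <- vapply(chains, chain_key, character(1))
  chains[order(keys, method = "radix")]
}

chain_terminal_id <- function(chain) chain$entity_ids[length(chain$entity_ids)]
chain_terminal_name <- function(chain) chain$entity_names[length(chain$entity_names)]

make_subgraph <- function(kg, chains) {
  chains <- sort_chains(chains)
  ids <- unique(unlist(lapply(chains, `[[`, "entity_ids")))
  ea <- lapply(ids, function(id) entity_attrs(kg, id))
  names(ea) <- ids
  structure(list(chains = chains, entity_attributes = ea),
            class = "kgqa_subgraph")
}

#' @export
print.kgqa_subgraph <- function(x, ...) {
  cat(sprintf("<kgqa subgraph: %d relational chains over %d entities>\n",
              length(x$chains), length(x$entity_attributes)))
  invisible(x)
}

# Does the attribute predicate hold for this entity (attributes given as a
# named list; the pseudo-key "name" reads the entity name, normalized)?
predicate_holds <- function(pred, attrs, name) {
  if (identical(pred$key, "name")) {
    if (pred$op == "exists") return(TRUE)
    if (pred$op == "equals")
      return(identical(normalize_name(name), normalize_name(as.character(pred$value))))
    return(FALSE)
  }
  v <- attrs[[pred$key]]
  if (is.null(v)) return(FALSE)
  switch(pred$op,
    exists = TRUE,
    equals = {
      if (is.numeric(v) || is.logical(v)) {
        pv <- parse_attr_value(as.character(pred$value))
        isTRUE(as.numeric(v) == suppressWarnings(as.numeric(pv))) ||
          identical(format_attr_value(v), format_attr_value(pv))
      } else {
        identical(normalize_name(as.character(v)),
                  normalize_name(as.character(pred$value)))
      }
    },
    ge = {
      nv <- suppressWarnings(as.numeric(v))
      isTRUE(nv >= suppressWarnings(as.numeric(pred$value)))
    },
    le = {
      nv <- suppressWarnings(as.numeric(v))
      isTRUE(nv <= suppressWarnings(as.numeric(pred$value)))
    },
    FALSE)
}

#' Execute a linear graph query
#'
#' Matches the query's anchored linear pattern against the graph. Matching is
#' undirected (stored edge direction is ignored during traversal but
#' preserved in the returned triplets), chains never revisit an entity
#' (simple-path semantics), and terminal attribute predicates are applied
#' before a chain is admitted. Returned chains are sorted by a canonical
#' (entity ids, relation labels) key so output order is reproducible.
#' Aggregate constraints (`max`/`min`) are deliberately *not* applied here;
#' they belong to the pruning stage.
#'
#' @param kg A `kgqa_kg`.
#' @param query A `kgqa_query` (see [graph_query()]).
#' @return A `kgqa_subgraph` with the matched relational chains and the
#'   attribute maps of every entity appearing in them. A query whose anchor
#'   type or name is absent yields an empty subgraph, not an error.
#' @export
execute_query <- function(kg, query) {
  stopifnot(inherits(query, "kgqa_query"))
  norm <- normalize_name(query$anchor_name)
  ids <- kg$name_index[[norm]]
  ids <- ids[vapply(ids, function(id) entity_type(kg, id) == query$anchor_type,
                    logical(1))]
  partial <- lapply(ids, function(id) list(ids = id, rows = integer(0)))

  hops <- query$hops
  for (h in seq_len(nrow(hops))) {
    lab <- hops$label[h]; ty <- hops$type[h]
    nxt <- list()
    for (p in partial) {
      last <- p$ids[length(p$ids)]
      for (r in kg$adj[[last]]) {
        e <- kg$edges[r, ]
        if (e$label != lab) next
        other <- if (e$head_id == last) e$tail_id else e$head_id
        # self-loop edges cannot extend a simple path
        if (other == last || other %in% p$ids) next
        if (entity_type(kg, other) != ty) next
        nxt[[length(nxt) + 1]] <- list(ids = c(p$ids, other), rows = c(p$rows, r))
      }
    }
    partial <- nxt
    if (length(partial) == 0) break
  }

  keep <- vapply(partial, function(p) {
    term <- p$ids[length(p$ids)]
    all(vapply(query$predicates, function(pr) {
      if (!identical(pr$aggregate, "none") && pr$op == "exists") {
        # aggregate predicates only require the key to exist at this stage
        predicate_holds(list(key = pr$key, op = "exists"), entity_attrs(kg, term),
                        entity_name(kg, term))
      } else {
        predicate_holds(pr, entity_attrs(kg, term), entity_name(kg, term))
      }
    }, logical(1)))
  }, logical(1))
  partial <- partial[keep]

  chains <- lapply(partial, function(p) make_chain(kg, p$ids, p$rows))
  make_subgraph(kg, chains)
}
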