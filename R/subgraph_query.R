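#' Construct a linear graph query
#'
#' A query anchors at a named entity of a given type, follows an ordered list
#' of (relation label, target type) hops taken from a relational path, and
#' constrains the terminal node with attribute predicates. `return_spec`
#' states what the answer projection is: terminal entity names, relation
#' labels along the chain, terminal attribute values, or whole chains.
#'
#' @param anchor_type,anchor_name Type and name of the anchored head entity.
#' @param hops data.frame with columns `label`, `type` (possibly zero rows
#'   for a zero-hop attribute query).
#' @param predicates List of [attr_predicate()] applied to the terminal node.
#' @param return_spec One of `"terminal-entities"`, `"relation-labels"`,
#'   `"terminal-attributes"`, `"chains"`.
#' @return An object of class `kgqa_query`.
#' @export
graph_query <- function(anchor_type, anchor_name,
                        hops = data.frame(label = character(0), type = character(0)),
                        predicates = list(),
                        return_spec = c("terminal-entities", "relation-labels",
                                        "terminal-attributes", "chains")) {
  return_spec <- match.arg(return_spec)
  hops <- as.data.frame(hops, stringsAsFactors = FALSE)
  if (nrow(hops) > 0) stopifnot(all(c("label", "type") %in% names(hops)))
  structure(list(anchor_type = anchor_type, anchor_name = anchor_name,
                 hops = hops, predicates = predicates,
                 return_spec = return_spec),
            class = "kgqa_query")
}

#' @export
print.kgqa_query <- function(x, ...) {
  cat(render_cypher(x), "\n")
  invisible(x)
}

# Attribute keys a terminal-attributes query projects (everything but the
# name pseudo-key).
query_attr_keys <- function(query) {
  keys <- vapply(query$predicates, `[[`, character(1), "key")
  unique(keys[keys != "name"])
}

#' Generate the graph query for a frame and an optimal path
#'
#' Deterministic mapping from (question frame, selected relational path) to
#' an executable query: the anchor comes from the chosen head, the hops are
#' the path's (label, type) pairs step for step, the terminal predicates are
#' the frame's tail predicates (plus a name-equality predicate when the tail
#' entity is known), and the return projection follows the reasoning
#' category: attribute questions return terminal attributes, known-tail
#' relation questions return relation labels, everything else returns
#' terminal entities.
#'
#' @param frame A resolved `kgqa_frame`.
#' @param op A `kgqa_path` starting at the head's entity type.
#' @param head_index Which head to anchor on (intersection questions run one
#'   query per head).
#' @return A `kgqa_query`.
#' @export
generate_query <- function(frame, op, head_index = 1L) {
  stopifnot(inherits(frame, "kgqa_frame"), inherits(op, "kgqa_path"))
  head <- frame$heads[head_index, ]
  if (is.na(head$etype))
    stop_config_error("frame heads must be resolved before query generation")
  if (!identical(op$types[1], head$etype))
    stop_config_error(sprintf(
      "path starts at type \"%s\" but head \"%s\" has type \"%s\"",
      op$types[1], head$name, head$etype))
  hops <- if (op$length > 0) {
    data.frame(label = op$labels, type = op$types[-1], stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), type = character(0))
  }
  preds <- frame$tail_predicates
  if (!is.null(frame$tail_name))
    preds <- c(preds, list(attr_predicate("name", "equals", frame$tail_name)))
  return_spec <- if (!is.null(frame$tail_name)) {
    "relation-labels"
  } else if (frame$category == "attribute") {
    "terminal-attributes"
  } else {
    "terminal-entities"
  }
  graph_query(head$etype, head$name, hops, preds, return_spec)
}

## --- canonical Cypher subset -------------------------------------------

escape_cypher_string <- function(s) {
  gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))
}

unescape_cypher_string <- function(s) {
  gsub("\\\\(.)", "\\1", s)
}

cypher_literal <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  sprintf('"%s"', escape_cypher_string(as.character(v)))
}

#' Render a query in the canonical Cypher subset
#'
#' Grammar: `MATCH (a:<Type> {name: "<Name>"})` followed by zero or more
#' undirected pattern elements `-[:<label>]-(x<i>:<Type>)` (with a
#' relationship variable `r<i>` when relation labels are returned), an
#' optional `WHERE` with `AND`-joined comparisons
#' `<var>.<key> <op> <literal>` (plus `IS NOT NULL` for existence), and a
#' `RETURN` of node names, relationship types, or attributes. Strings are
#' double-quoted with backslash escapes. Patterns leave edge direction
#' unconstrained, consistent with the undirected schema graph. The rendering
#' is canonical: [parse_cypher()] followed by `render_cypher()` reproduces
#' the text byte for byte.
#'
#' @param query A `kgqa_query`.
#' @return A character scalar.
#' @export
#' @examples
#' q <- graph_query("drug", "diethylstilbestrol",
#'                  data.frame(label = "treats", type = "disease"))
#' render_cypher(q)
render_cypher <- function(query) {
  stopifnot(inherits(query, "kgqa_query"))
  nh <- nrow(query$hops)
  want_rel <- query$return_spec == "relation-labels"
  pat <- sprintf('MATCH (a:%s {name: "%s"})', query$anchor_type,
                 escape_cypher_string(query$anchor_name))
  for (i in seq_len(nh)) {
    pat <- paste0(pat, sprintf("-[%s:%s]-(x%d:%s)",
                               if (want_rel) sprintf("r%d", i) else "",
                               query$hops$label[i], i, query$hops$type[i]))
  }
  term <- if (nh == 0) "a" else sprintf("x%d", nh)

  clauses <- character(0)
  for (p in query$predicates) {
    if (p$op == "exists") {
      # redundant when the attribute itself is returned
      if (query$return_spec == "terminal-attributes") next
      clauses <- c(clauses, sprintf("%s.%s IS NOT NULL", term, p$key))
    } else {
      sym <- switch(p$op, equals = "=", ge = ">=", le = "<=")
      clauses <- c(clauses, sprintf("%s.%s %s %s", term, p$key, sym,
                                    cypher_literal(p$value)))
    }
  }
  where <- if (length(clauses) > 0) paste(" WHERE", paste(clauses, collapse = " AND ")) else ""

  ret <- switch(query$return_spec,
    "terminal-entities" = sprintf("%s.name", term),
    "relation-labels" = paste(sprintf("type(r%d)", seq_len(max(nh, 1))), collapse = ", "),
    "terminal-attributes" = {
      keys <- sort_c(query_attr_keys(query))
      if (length(keys) == 0) stop_config_error("attribute query has no attribute keys")
      paste(sprintf("%s.%s", term, keys), collapse = ", ")
    },
    "chains" = paste(c("a.name", sprintf("x%d.name", seq_len(nh))), collapse = ", "))
  paste0(pat, where, " RETURN ", ret)
}

#' Parse a query rendered in the canonical Cypher subset
#'
#' Inverse of [render_cypher()] on the canonical grammar; used to validate
#' model-generated query text (out-of-grammar responses are rejected) and in
#' round-trip tests. Aggregate annotations are not part of the surface
#' grammar, so parsed predicates carry `aggregate = "none"`.
#'
#' @param text Query text.
#' @return A `kgqa_query`.
#' @export
parse_cypher <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  str_re <- '"((?:[^"\\\\]|\\\\.)*)"'
  m <- regmatches(text, regexec(
    paste0('^MATCH \\(a:([A-Za-z_][A-Za-z0-9_-]*) \\{name: ', str_re, '\\}\\)'),
    text))[[1]]
  if (length(m) == 0) stop_config_error("not in the canonical Cypher subset (anchor)")
  anchor_type <- m[2]
  anchor_name <- unescape_cypher_string(m[3])
  rest <- substr(text, nchar(m[1]) + 1, nchar(text))

  hops <- data.frame(label = character(0), type = character(0),
                     stringsAsFactors = FALSE)
  hop_re <- "^-\\[(r[0-9]+)?:([A-Za-z_][A-Za-z0-9_-]*)\\]-\\(x([0-9]+):([A-Za-z_][A-Za-z0-9_-]*)\\)"
  saw_rel_var <- FALSE
  repeat {
    hm <- regmatches(rest, regexec(hop_re, rest))[[1]]
    if (length(hm) == 0) break
    if (nzchar(hm[2])) saw_rel_var <- TRUE
    hops <- rbind(hops, data.frame(label = hm[3], type = hm[5],
                                   stringsAsFactors = FALSE))
    rest <- substr(rest, nchar(hm[1]) + 1, nchar(rest))
  }

  where_part <- NULL
  rm <- regmatches(rest, regexec("^(?: WHERE (.*))? RETURN (.*)$", rest))[[1]]
  if (length(rm) == 0) stop_config_error("not in the canonical Cypher subset (clauses)")
  if (nzchar(rm[2])) where_part <- rm[2]
  ret_part <- rm[3]

  predicates <- list()
  if (!is.null(where_part)) {
    for (cl in strsplit(where_part, " AND ", fixed = TRUE)[[1]]) {
      em <- regmatches(cl, regexec("^[ax][0-9]*\\.([A-Za-z_][A-Za-z0-9_]*) IS NOT NULL$", cl))[[1]]
      if (length(em) > 0) {
        predicates <- c(predicates, list(attr_predicate(em[2], "exists")))
        next
      }
      em <- regmatches(cl, regexec(
        paste0("^[ax][0-9]*\\.([A-Za-z_][A-Za-z0-9_]*) (=|>=|<=) (.*)$"), cl))[[1]]
      if (length(em) == 0) stop_config_error(sprintf("unparseable WHERE clause: %s", cl))
      key <- em[2]
      op <- switch(em[3], "=" = "equals", ">=" = "ge", "<=" = "le")
      lit <- em[4]
      value <- if (grepl('^".*"$', lit)) {
        unescape_cypher_string(substr(lit, 2, nchar(lit) - 1))
      } else if (lit %in% c("true", "false")) {
        identical(lit, "true")
      } else {
        as.numeric(lit)
      }
      predicates <- c(predicates, list(attr_predicate(key, op, value)))
    }
  }

  return_spec <- if (grepl("^type\\(r[0-9]+\\)", ret_part) || saw_rel_var) {
    "relation-labels"
  } else {
    items <- strsplit(ret_part, ", ", fixed = TRUE)[[1]]
    keys <- sub("^[ax][0-9]*\\.", "", items)
    if (all(keys == "name")) {
      if (length(items) > 1) "chains" else "terminal-entities"
    } else {
      # the returned attribute keys imply existence predicates not repeated
      # in the WHERE clause; reconstruct them
      have <- vapply(predicates, `[[`, character(1), "key")
      for (k in keys[!keys %in% have])
        predicates <- c(predicates, list(attr_predicate(k, "exists")))
      "terminal-attributes"
    }
  }
  graph_query(anchor_type, anchor_name, hops, predicates, return_spec)
}

#' Retrieve one subgraph per head
#'
#' Runs [generate_query()] and [execute_query()] for each head of the frame.
#' Intersection frames therefore produce one subgraph per head; the
#' generated query is attached to each subgraph as attribute `"query"`.
#'
#' @param kg A `kgqa_kg`.
#' @param frame A resolved `kgqa_frame`.
#' @param ops A single `kgqa_path` or a list with one path per head.
#' @return List of `kgqa_subgraph`, one per head.
#' @export
run_retrieval <- function(kg, frame, ops) {
  n <- nrow(frame$heads)
  if (inherits(ops, "kgqa_path")) ops <- rep(list(ops), n)
  stopifnot(length(ops) == n)
  lapply(seq_len(n), function(i) {
    q <- generate_query(frame, ops[[i]], i)
    sg <- execute_query(kg, q)
    attr(sg, "query") <- q
    sg
  })
}

#' Construct an answer set
#'
#' @param items Character vector of answer items (entity names, relation
#'   labels or attribute values).
#' @param provenance Named list mapping each item to the relational chains
#'   supporting it.
#' @param return_spec The projection that produced the items.
#' @return An object of class `kgqa_answer_set`.
#' @export
answer_set <- function(items, provenance = stats::setNames(vector("list", length(items)), items),
                       return_spec = "terminal-entities") {
  items <- as.character(items)
  structure(list(items = items, provenance = provenance,
                 return_spec = return_spec),
            class = "kgqa_answer_set")
}

#' @export
print.kgqa_answer_set <- function(x, ...) {
  cat(sprintf("<kgqa answer set (%s)> {%s}\n", x$return_spec,
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' Intersect answer sets
#'
#' The tail set of an intersection question is the set intersection of the
#' per-head tail sets; provenance of each surviving item is merged across
#' inputs. Commutative, associative and idempotent.
#'
#' @param answer_sets Non-empty list of `kgqa_answer_set`.
#' @return A `kgqa_answer_set`.
#' @export
intersect_answers <- function(answer_sets) {
  stopifnot(length(answer_sets) >= 1)
  items <- Reduce(intersect, lapply(answer_sets, `[[`, "items"))
  items <- sort_c(unique(items))
  prov <- lapply(items, function(it) {
    chains <- list()
    for (s in answer_sets) {
      if (!is.null(s$provenance[[it]])) chains <- c(chains, s$provenance[[it]])
    }
    chains
  })
  names(prov) <- items
  answer_set(items, prov, answer_sets[[1]]$return_spec)
}
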