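#' Build the schema graph of a knowledge graph
#'
#' The schema graph abstracts the instance-level graph to the type level: its
#' nodes are the entity types occurring in the graph and its edges are the
#' relation labels observed between pairs of types. It is undirected (edge
#' endpoints are stored as a canonically ordered pair) and a multigraph:
#' distinct relation labels between the same pair of types are kept as
#' parallel edges.
#'
#' @param kg A `kgqa_kg`.
#' @return An object of class `kgqa_schema` with fields `types` (character)
#'   and `edges` (data.frame `type_a`, `type_b`, `label`; `type_a <= type_b`).
#' @export
build_schema_graph <- function(kg) {
  types <- sort_c(unique(kg$nodes$etype))
  if (nrow(kg$edges) > 0) {
    t1 <- kg$nodes$etype[kg$row_of[kg$edges$head_id]]
    t2 <- kg$nodes$etype[kg$row_of[kg$edges$tail_id]]
    edges <- data.frame(type_a = pmin(t1, t2), type_b = pmax(t1, t2),
                        label = kg$edges$label, stringsAsFactors = FALSE)
    edges <- unique(edges)
    edges <- edges[order(edges$type_a, edges$type_b, edges$label,
                         method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(type_a = character(0), type_b = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  }
  structure(list(types = types, edges = edges), class = "kgqa_schema")
}

#' @export
print.kgqa_schema <- function(x, ...) {
  cat(sprintf("<kgqa schema graph: %d entity types, %d typed edges>\n",
              length(x$types), nrow(x$edges)))
  invisible(x)
}

#' Export a schema graph as an edge-list data.frame
#' @param schema A `kgqa_schema`.
#' @return The schema's edge table (`type_a`, `type_b`, `label`).
#' @export
schema_edgelist <- function(schema) schema$edges

# Neighbouring types of `t` (by any label).
type_neighbors <- function(schema, t) {
  e <- schema$edges
  unique(c(e$type_b[e$type_a == t & e$type_b != t],
           e$type_a[e$type_b == t & e$type_a != t]))
}

types_adjacent <- function(schema, t1, t2) {
  a <- pmin(t1, t2); b <- pmax(t1, t2)
  any(schema$edges$type_a == a & schema$edges$type_b == b)
}

labels_between <- function(schema, t1, t2) {
  a <- pmin(t1, t2); b <- pmax(t1, t2)
  sort_c(schema$edges$label[schema$edges$type_a == a & schema$edges$type_b == b])
}

#' Construct a relational path
#'
#' An alternating sequence of entity types and relation labels,
#' `t1 -r1- t2 -r2- ... -tk`; a zero-hop path is a single type.
#'
#' @param types Character vector of entity types (length k >= 1).
#' @param labels Character vector of relation labels (length k - 1).
#' @return An object of class `kgqa_path`.
#' @export
rel_path <- function(types, labels = character(0)) {
  stopifnot(length(types) >= 1, length(labels) == length(types) - 1)
  structure(list(types = as.character(types), labels = as.character(labels),
                 length = length(labels)), class = "kgqa_path")
}

#' @export
print.kgqa_path <- function(x, ...) {
  cat(sprintf("<kgqa path, %d hop(s)> %s\n", x$length, verbalize_path(x)))
  invisible(x)
}

#' Verbalize a relational path
#'
#' Canonical text rendering used both for display and as embedder input:
#' types and relation labels joined in step order with single spaces, with
#' hyphen/underscore runs replaced by spaces.
#'
#' @param sp A `kgqa_path`.
#' @return A character scalar.
#' @export
#' @examples
#' verbalize_path(rel_path(c("drug", "disease"), "treats"))
verbalize_path <- function(sp) {
  stopifnot(inherits(sp, "kgqa_path"))
  k <- length(sp$types)
  out <- character(2 * k - 1)
  out[seq(1, 2 * k - 1, by = 2)] <- sp$types
  if (k > 1) out[seq(2, 2 * k - 2, by = 2)] <- sp$labels
  gsub("[-_]+", " ", paste(out, collapse = " "))
}

#' Enumerate all shortest relational paths between two entity types
#'
#' Breadth-first search from the head type layers the schema graph by hop
#' distance; tracking *every* predecessor of a node in the previous layer
#' (rather than the single BFS tree parent) lets the search enumerate every
#' minimal-hop node sequence to the tail type. Each sequence is then expanded
#' into one candidate per combination of relation labels available along its
#' edges, so parallel labels yield distinct candidates. Only minimal-length
#' paths are returned; if the tail type is unreachable the result is empty
#' and no longer paths are searched.
#'
#' @param schema A `kgqa_schema`.
#' @param h_t,t_t Head and tail entity types (must be schema nodes).
#' @return A list of `kgqa_path`, sorted by verbalization; a single zero-hop
#'   path when `h_t == t_t`; an empty list when `t_t` is unreachable.
#' @export
candidate_paths <- function(schema, h_t, t_t) {
  for (t in c(h_t, t_t)) {
    if (!t %in% schema$types)
      kgqa_stop("kgqa_unknown_type",
                sprintf("unknown entity type: \"%s\"", t), type = t)
  }
  if (identical(h_t, t_t)) return(list(rel_path(h_t)))

  dist <- stats::setNames(rep(NA_integer_, length(schema$types)), schema$types)
  dist[h_t] <- 0L
  queue <- h_t
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in type_neighbors(schema, u)) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  if (is.na(dist[t_t])) return(list())

  # every minimal node sequence, by backtracking over all predecessors
  sequences <- list()
  backtrack <- function(node, acc) {
    if (node == h_t) {
      sequences[[length(sequences) + 1]] <<- c(h_t, acc)
      return(invisible(NULL))
    }
    preds <- type_neighbors(schema, node)
    preds <- preds[!is.na(dist[preds]) & dist[preds] == dist[node] - 1L]
    for (p in sort_c(preds)) backtrack(p, c(node, acc))
  }
  backtrack(t_t, character(0))

  paths <- list()
  for (sq in sequences) {
    label_opts <- lapply(seq_len(length(sq) - 1),
                         function(i) labels_between(schema, sq[i], sq[i + 1]))
    combos <- expand.grid(rev(label_opts), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_along(label_opts)), drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      paths[[length(paths) + 1]] <- rel_path(sq, unlist(combos[r, ], use.names = FALSE))
    }
  }
  verb <- vapply(paths, verbalize_path, character(1))
  paths[order(verb, method = "radix")]
}

#' Cosine similarity of two embedding vectors
#'
#' `sim(u, v) = (u . v) / (||u|| ||v||)`, the standard angular similarity in
#' embedding space; symmetric, bounded in `[-1, 1]` and invariant to positive
#' rescaling of either argument.
#'
#' @param u,v Numeric vectors of equal dimension, neither all-zero.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop_config_error(sprintf("embedding dimension mismatch: %d vs %d",
                              length(u), length(v)))
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    kgqa_stop("kgqa_degenerate_embedding", "all-zero embedding vector")
  sum(u * v) / (nu * nv)
}

#' Deterministic bag-of-tokens hashing embedder
#'
#' The reference embedder backend: tokens (case-folded, split on
#' non-alphanumeric runs) are feature-hashed into a fixed-dimension count
#' vector which is then L2-normalized. It is deterministic, order-insensitive
#' (a bag, not a sequence) and produces a non-zero vector for any text with
#' at least one token -- exactly the contract the path-selection stage needs
#' for offline, reproducible runs. Sentence-embedding models can be dropped
#' in as alternative backends: any function `text -> numeric` of constant
#' dimension satisfies the contract.
#'
#' @param dim Embedding dimension (default 256).
#' @return A function `text -> numeric(dim)`.
#' @export
hash_embedder <- function(dim = 256L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2)
  function(text) {
    stopifnot(is.character(text), length(text) == 1)
    if (!nzchar(trimws(text)))
      kgqa_stop("kgqa_degenerate_embedding", "cannot embed empty text")
    toks <- tokenize_text(text)
    if (length(toks) == 0)
      kgqa_stop("kgqa_degenerate_embedding", "text has no alphanumeric tokens")
    idx <- vapply(toks, function(tok) {
      h <- 0
      for (b in utf8ToInt(tok)) h <- (h * 31 + b) %% 2147483647
      as.integer(h %% dim) + 1L
    }, integer(1))
    v <- tabulate(idx, nbins = dim)
    v / sqrt(sum(v * v))
  }
}

#' Select the optimal relational path for a question
#'
#' Scores every candidate path by the cosine similarity between the
#' embedding of the question and the embedding of the verbalized path, and
#' returns the argmax. Ties (within 1e-12) are broken by the
#' lexicographically smallest verbalization, so the result does not depend
#' on candidate order.
#'
#' @param question Question text.
#' @param candidates Non-empty list of `kgqa_path`.
#' @param embedder Embedding backend, a function `text -> numeric`; default
#'   [hash_embedder()].
#' @return The selected `kgqa_path`, with the score in attribute
#'   `"similarity"`.
#' @export
select_optimal_path <- function(question, candidates, embedder = hash_embedder()) {
  if (length(candidates) == 0)
    kgqa_stop("kgqa_no_path", "no candidate relational paths to select from")
  if (length(candidates) == 1) {
    p <- candidates[[1]]
    attr(p, "similarity") <- NA_real_
    return(p)
  }
  qv <- embedder(question)
  verb <- vapply(candidates, verbalize_path, character(1))
  scores <- vapply(verb, function(tx) cosine_similarity(qv, embedder(tx)),
                   numeric(1), USE.NAMES = FALSE)
  best <- max(scores)
  tied <- which(scores >= best - 1e-12)
  sel <- tied[order(verb[tied], method = "radix")][1]
  p <- candidates[[sel]]
  attr(p, "similarity") <- scores[sel]
  p
}
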