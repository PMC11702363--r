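# Independent oracles. Each re-derives an expected result by a different
# algorithm than the implementation under test.

# -- exhaustive shortest-path enumeration (DFS over labelled edges) --------

rand_schema <- function(max_types = 8, max_edges = 20) {
  k <- sample(2:max_types, 1)
  types <- paste0("t", seq_len(k))
  n_e <- sample(1:max_edges, 1)
  labels <- paste0("r", 1:6)
  a <- types[sample.int(k, n_e, replace = TRUE)]
  b <- types[sample.int(k, n_e, replace = TRUE)]
  keep <- a != b
  edges <- unique(data.frame(type_a = pmin(a[keep], b[keep]),
                             type_b = pmax(a[keep], b[keep]),
                             label = sample(labels, sum(keep), replace = TRUE),
                             stringsAsFactors = FALSE))
  if (nrow(edges) == 0)
    edges <- data.frame(type_a = types[1], type_b = types[2], label = "r1",
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$type_a, edges$type_b, edges$label,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(types = types, edges = edges), class = "kgqa_schema")
}

# All simple label-level paths from h to t by depth-first search; keep the
# minimal hop count only. Returns verbalizations (sorted).
dfs_shortest_verbalized <- function(schema, h, t) {
  if (identical(h, t)) return(verbalize_path(rel_path(h)))
  e <- schema$edges
  found <- list()
  recurse <- function(node, types_acc, labels_acc) {
    inc <- which(e$type_a == node | e$type_b == node)
    for (i in inc) {
      other <- if (e$type_a[i] == node) e$type_b[i] else e$type_a[i]
      if (other %in% types_acc) next
      ty <- c(types_acc, other)
      la <- c(labels_acc, e$label[i])
      if (other == t) {
        found[[length(found) + 1]] <<- rel_path(ty, la)
      } else {
        recurse(other, ty, la)
      }
    }
  }
  recurse(h, h, character(0))
  if (length(found) == 0) return(character(0))
  lens <- vapply(found, function(p) p$length, numeric(1))
  sort(vapply(found[lens == min(lens)], verbalize_path, character(1)),
       method = "radix")
}

# -- LCS oracles -----------------------------------------------------------

is_subseq <- function(x, b) {
  if (length(x) == 0) return(TRUE)
  j <- 1
  for (tok in b) {
    if (tok == x[j]) {
      j <- j + 1
      if (j > length(x)) return(TRUE)
    }
  }
  FALSE
}

# Brute force: enumerate every subsequence of a (|a| <= ~12).
brute_lcs <- function(a, b) {
  n <- length(a)
  if (n == 0 || length(b) == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- a[bitwAnd(bitwShiftL(1, 0:(n - 1)), mask) != 0]
    if (length(sel) > best && is_subseq(sel, b)) best <- length(sel)
  }
  best
}

# Established implementation: Biostrings global alignment with zero gap cost
# and a prohibitive mismatch penalty scores exactly the LCS length.
biostrings_lcs <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  vocab <- unique(c(a, b))
  stopifnot(length(vocab) <= 26)
  enc <- function(x) paste(LETTERS[match(x, vocab)], collapse = "")
  mat <- matrix(-1000L, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1L
  as.integer(Biostrings::pairwiseAlignment(
    enc(a), enc(b), type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE))
}

# -- brute-force chain matcher --------------------------------------------

# Enumerate all label/type-consistent simple walks straight off the edge
# table (no adjacency index, no recursion sharing with execute_query).
brute_match_chains <- function(kg, query) {
  e <- kg$edges
  anchors <- kg$nodes$id[kg$nodes$etype == query$anchor_type &
                           normalize_name(kg$nodes$name) ==
                             normalize_name(query$anchor_name)]
  walks <- lapply(anchors, function(a) list(ids = a, rows = integer(0)))
  for (h in seq_len(nrow(query$hops))) {
    nxt <- list()
    for (w in walks) {
      last <- w$ids[length(w$ids)]
      for (r in seq_len(nrow(e))) {
        if (e$label[r] != query$hops$label[h]) next
        other <- if (e$head_id[r] == last) {
          e$tail_id[r]
        } else if (e$tail_id[r] == last) {
          e$head_id[r]
        } else {
          next
        }
        if (other %in% w$ids) next
        if (kg$nodes$etype[kg$row_of[[other]]] != query$hops$type[h]) next
        nxt[[length(nxt) + 1]] <- list(ids = c(w$ids, other), rows = c(w$rows, r))
      }
    }
    walks <- nxt
  }
  # terminal predicates, re-evaluated naively
  ok <- vapply(walks, function(w) {
    term <- w$ids[length(w$ids)]
    attrs <- kg$attrs[[term]]
    nm <- kg$nodes$name[kg$row_of[[term]]]
    all(vapply(query$predicates, function(p) {
      if (identical(p$key, "name")) {
        p$op != "equals" || normalize_name(nm) == normalize_name(as.character(p$value))
      } else if (p$op == "exists" || !identical(p$aggregate, "none")) {
        !is.null(attrs[[p$key]])
      } else if (p$op == "equals") {
        !is.null(attrs[[p$key]]) &&
          tolower(as.character(attrs[[p$key]])) == tolower(as.character(p$value))
      } else if (p$op == "ge") {
        !is.null(attrs[[p$key]]) && as.numeric(attrs[[p$key]]) >= as.numeric(p$value)
      } else {
        !is.null(attrs[[p$key]]) && as.numeric(attrs[[p$key]]) <= as.numeric(p$value)
      }
    }, logical(1)))
  }, logical(1))
  walks <- walks[ok]
  sort(vapply(walks, function(w) paste(w$ids, collapse = "|"), character(1)),
       method = "radix")
}

chain_id_signature <- function(subgraph) {
  sort(vapply(subgraph$chains, function(ch) paste(ch$entity_ids, collapse = "|"),
              character(1)), method = "radix")
}

# -- random queries for the Cypher round-trip ------------------------------

rand_query <- function() {
  types <- c("drug", "gene", "disease", "mutation", "clinical_trial")
  labels <- c("treats", "inhibits", "has_mutation", "of_gene", "resistant_to",
              "has_trial")
  names_pool <- c("carteolol", "ALK p.L1196M", 'quo "ted"', "back\\slash",
                  "plain name", "NCT0000002")
  nh <- sample(0:3, 1)
  hops <- if (nh > 0) {
    data.frame(label = sample(labels, nh, replace = TRUE),
               type = sample(types, nh, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), type = character(0))
  }
  preds <- list()
  for (i in seq_len(sample(0:2, 1))) {
    op <- sample(c("equals", "ge", "le", "exists"), 1)
    preds[[i]] <- if (op == "exists") {
      attr_predicate(sample(c("maximum_age", "targeted_therapy"), 1), "exists")
    } else if (op == "equals") {
      attr_predicate("status", "equals", sample(names_pool, 1))
    } else {
      attr_predicate("maximum_age", op, sample(1:99, 1))
    }
  }
  rs <- if (nh > 0) {
    sample(c("terminal-entities", "relation-labels", "chains",
             if (length(preds) > 0 && any(vapply(preds, function(p)
               p$key != "name", logical(1)))) "terminal-attributes"), 1)
  } else {
    if (length(preds) > 0 && any(vapply(preds, function(p) p$key != "name",
                                        logical(1)))) {
      sample(c("terminal-entities", "terminal-attributes"), 1)
    } else {
      "terminal-entities"
    }
  }
  graph_query(sample(types, 1), sample(names_pool, 1), hops, preds, rs)
}
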