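#' Prune retrieved chains against the question frame
#'
#' Retains exactly the chains that (a) start at an entity whose normalized
#' name equals the anchored head name, (b) follow the selected relational
#' path's type and label sequence step for step, and (c) end at an entity
#' satisfying every tail predicate. Aggregate predicates (`max`/`min`)
#' additionally reduce the surviving set to the chains whose terminal
#' attains the extremum of the keyed attribute. Pruning is monotone (output
#' chains are a subset of the input) and idempotent.
#'
#' @param subgraph A `kgqa_subgraph`.
#' @param frame The resolved `kgqa_frame` the subgraph was retrieved for.
#' @param op The `kgqa_path` the retrieval followed.
#' @param head_index Which head this subgraph belongs to.
#' @return The pruned `kgqa_subgraph` (possibly with zero chains).
#' @export
prune_chains <- function(subgraph, frame, op, head_index = 1L) {
  stopifnot(inherits(subgraph, "kgqa_subgraph"), inherits(frame, "kgqa_frame"),
            inherits(op, "kgqa_path"))
  head_name <- normalize_name(frame$heads$name[head_index])

  ok <- vapply(subgraph$chains, function(ch) {
    if (!identical(normalize_name(ch$entity_names[1]), head_name)) return(FALSE)
    if (!identical(unname(ch$entity_types), op$types)) return(FALSE)
    if (!identical(unname(ch$steps$label), op$labels)) return(FALSE)
    term <- chain_terminal_id(ch)
    attrs <- subgraph$entity_attributes[[term]]
    all(vapply(frame$tail_predicates, function(p) {
      if (!identical(p$aggregate, "none") && p$op == "exists") {
        predicate_holds(list(key = p$key, op = "exists"), attrs,
                        chain_terminal_name(ch))
      } else {
        predicate_holds(p, attrs, chain_terminal_name(ch))
      }
    }, logical(1)))
  }, logical(1))
  chains <- subgraph$chains[ok]

  for (p in frame$tail_predicates) {
    if (identical(p$aggregate, "none") || length(chains) == 0) next
    vals <- vapply(chains, function(ch) {
      v <- subgraph$entity_attributes[[chain_terminal_id(ch)]][[p$key]]
      if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
    }, numeric(1))
    if (all(is.na(vals))) {
      chains <- list()
      break
    }
    target <- if (identical(p$aggregate, "max")) max(vals, na.rm = TRUE) else min(vals, na.rm = TRUE)
    chains <- chains[!is.na(vals) & vals == target]
  }

  ids <- unique(unlist(lapply(chains, `[[`, "entity_ids")))
  structure(list(chains = chains,
                 entity_attributes = subgraph$entity_attributes[
                   names(subgraph$entity_attributes) %in% ids]),
            class = "kgqa_subgraph")
}

#' Derive the answer set from a pruned subgraph
#'
#' Projects the surviving chains according to the query's return
#' specification: terminal entity names, the relation labels traversed (for
#' relation-seeking questions), terminal attribute values, or whole chains.
#' Items are deduplicated and returned in a deterministic sorted order, each
#' with the chains that support it as provenance. Relation labels and
#' multi-label sequences are rendered with hyphens/underscores spaced, as in
#' chain sentences.
#'
#' @param subgraph A pruned `kgqa_subgraph`.
#' @param query The `kgqa_query` that produced it.
#' @return A `kgqa_answer_set`.
#' @export
derive_answer_set <- function(subgraph, query) {
  stopifnot(inherits(subgraph, "kgqa_subgraph"), inherits(query, "kgqa_query"))
  rs <- query$return_spec
  items <- character(0)
  prov <- list()
  add <- function(item, chain) {
    if (!item %in% items) {
      items <<- c(items, item)
      prov[[item]] <<- list()
    }
    prov[[item]] <<- c(prov[[item]], list(chain))
  }
  for (ch in subgraph$chains) {
    its <- switch(rs,
      "terminal-entities" = chain_terminal_name(ch),
      "relation-labels" = paste(gsub("[-_]+", " ", ch$steps$label), collapse = " -> "),
      "terminal-attributes" = {
        attrs <- subgraph$entity_attributes[[chain_terminal_id(ch)]]
        keys <- query_attr_keys(query)
        vals <- character(0)
        for (k in keys) if (!is.null(attrs[[k]])) vals <- c(vals, format_attr_value(attrs[[k]]))
        vals
      },
      "chains" = paste(ch$entity_names, collapse = " -> "))
    for (it in its) add(it, ch)
  }
  ord <- order(items, method = "radix")
  answer_set(items[ord], prov[items[ord]], rs)
}

#' Verbalize a relational chain as a sentence fragment
#'
#' Deterministic template: each triplet is rendered in its *stored*
#' orientation as `"<head name> <label words> <tail name>"` (label
#' underscores and hyphens become spaces) and triplets are joined with
#' `", and "`.
#'
#' @param chain A non-empty `kgqa_chain`.
#' @return A character scalar.
#' @export
chain_to_sentence <- function(chain) {
  stopifnot(inherits(chain, "kgqa_chain"))
  if (nrow(chain$steps) == 0)
    stop_config_error("cannot verbalize an empty relational chain")
  parts <- sprintf("%s %s %s", chain$steps$head_name,
                   gsub("[-_]+", " ", chain$steps$label),
                   chain$steps$tail_name)
  paste(parts, collapse = ", and ")
}

# Sentence for one chain under a given return projection. For attribute
# projections the keyed value is appended so the answer item itself is
# grounded in a sentence; a bare-entity chain (zero-hop attribute lookup)
# becomes "<name> <key words> is <value>".
sentence_for_chain <- function(chain, subgraph, return_spec = "terminal-entities",
                               attr_keys = character(0)) {
  bare <- nrow(chain$steps) == 0
  if (return_spec == "terminal-attributes") {
    attrs <- subgraph$entity_attributes[[chain_terminal_id(chain)]]
    frags <- character(0)
    for (k in attr_keys) {
      if (is.null(attrs[[k]])) next
      frags <- c(frags, sprintf("%s %s is %s", chain_terminal_name(chain),
                                gsub("[-_]+", " ", k), format_attr_value(attrs[[k]])))
    }
    if (bare) return(paste(frags, collapse = ", and "))
    return(paste(c(chain_to_sentence(chain), frags), collapse = ", and "))
  }
  if (bare) return(chain$entity_names[1])
  chain_to_sentence(chain)
}

#' Compose the final answer
#'
#' Default deterministic composer: a summary sentence listing the answer set
#' (`"Answer: x, y."`), followed by the per-chain evidence sentences. An
#' empty answer set yields the configured no-answer message -- never a
#' fabricated answer. A model-backed composer can be passed as `backend`
#' (`function(sentences, items) -> text`); its output is accepted only if it
#' contains every answer item verbatim, otherwise it is rejected and an
#' error is raised.
#'
#' @param sentences Character vector of evidence sentences.
#' @param aset A `kgqa_answer_set`.
#' @param backend Optional composer backend.
#' @param no_answer_text Message used when the answer set is empty.
#' @return An object of class `kgqa_answer` with fields `answer_set`,
#'   `sentences`, `text`.
#' @export
compose_answer <- function(sentences, aset, backend = NULL,
                           no_answer_text = default_config()$no_answer_text) {
  stopifnot(inherits(aset, "kgqa_answer_set"))
  if (length(aset$items) == 0) {
    return(structure(list(answer_set = aset, sentences = character(0),
                          text = no_answer_text), class = "kgqa_answer"))
  }
  if (is.null(backend)) {
    summary <- sprintf("Answer: %s.", paste(aset$items, collapse = ", "))
    text <- if (length(sentences) > 0) {
      paste0(summary, " Evidence: ", paste(paste0(sentences, "."), collapse = " "))
    } else {
      summary
    }
  } else {
    text <- backend(sentences, aset$items)
    missing <- aset$items[!vapply(aset$items, function(it) grepl(it, text, fixed = TRUE),
                                  logical(1))]
    if (length(missing) > 0)
      stop_config_error(sprintf(
        "composer backend output omitted answer item(s): %s",
        paste(missing, collapse = ", ")))
  }
  structure(list(answer_set = aset, sentences = sentences, text = text),
            class = "kgqa_answer")
}

#' @export
print.kgqa_answer <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Serialize an answer (with pipeline context) to JSON
#'
#' @param answer A `kgqa_answer`, typically from [answer_question()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
answer_to_json <- function(answer, pretty = TRUE) {
  obj <- list(
    question = attr(answer, "question"),
    answer_set = answer$answer_set$items,
    sentences = answer$sentences,
    text = answer$text,
    optimal_path = attr(answer, "optimal_paths"),
    cypher = attr(answer, "cypher"))
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty, digits = NA)
}
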