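#' Construct a tail attribute predicate
#'
#' Predicates constrain the terminal entity of a retrieval: an attribute must
#' exist, equal a value, or compare numerically (`ge`/`le`); an optional
#' aggregate (`max`/`min`) asks for the arg-extremum over the retrieved
#' terminal set (resolved at the pruning stage, not inside the query engine).
#'
#' @param key Attribute key; the pseudo-key `"name"` addresses the entity
#'   name itself.
#' @param op One of `"equals"`, `"ge"`, `"le"`, `"exists"`.
#' @param value Comparison value; required unless `op = "exists"`.
#' @param aggregate One of `"none"`, `"max"`, `"min"`.
#' @return An object of class `kgqa_predicate`.
#' @export
attr_predicate <- function(key, op = c("equals", "ge", "le", "exists"),
                           value = NULL, aggregate = c("none", "max", "min")) {
  op <- match.arg(op)
  aggregate <- match.arg(aggregate)
  if (op == "exists" && !is.null(value))
    stop_config_error("an 'exists' predicate takes no value")
  if (op != "exists" && is.null(value))
    stop_config_error(sprintf("predicate op '%s' requires a value", op))
  structure(list(key = key, op = op, value = value, aggregate = aggregate),
            class = "kgqa_predicate")
}

#' Construct a question frame
#'
#' The frame is the structured decomposition of a question: the head entity
#' name(s) with their (later-resolved) types, the sought tail entity type,
#' an optional known tail entity name (relation-seeking questions), tail
#' attribute predicates, and the reasoning category.
#'
#' @param question Raw question text.
#' @param heads Character vector of head entity names (at least one).
#' @param tail_type Sought tail entity type, or `NULL`.
#' @param tail_name Known tail entity name, or `NULL`.
#' @param tail_predicates List of [attr_predicate()] objects.
#' @param category One of `"one-hop"`, `"multihop"`, `"intersection"`,
#'   `"attribute"`.
#' @return An object of class `kgqa_frame`.
#' @export
question_frame <- function(question, heads, tail_type = NULL, tail_name = NULL,
                           tail_predicates = list(),
                           category = c("one-hop", "multihop", "intersection",
                                        "attribute")) {
  category <- match.arg(category)
  if (length(heads) < 1) stop_extraction_failure(question)
  if (length(heads) >= 2 && category != "intersection")
    stop_config_error("frames with two or more heads must have category 'intersection'")
  if (category == "intersection" && length(heads) < 2)
    stop_config_error("an intersection frame needs at least two heads")
  if (is.null(tail_type) && is.null(tail_name) && category != "attribute")
    stop_config_error("tail_type and tail_name may both be absent only for attribute frames")
  structure(list(
    question = question,
    heads = data.frame(name = as.character(heads), etype = NA_character_,
                       stringsAsFactors = FALSE),
    tail_type = tail_type, tail_name = tail_name,
    tail_predicates = tail_predicates, category = category),
    class = "kgqa_frame")
}

#' @export
print.kgqa_frame <- function(x, ...) {
  cat(sprintf("<kgqa frame [%s]> heads: %s; tail type: %s%s%s\n",
              x$category,
              paste(sprintf("%s(%s)", x$heads$name,
                            ifelse(is.na(x$heads$etype), "?", x$heads$etype)),
                    collapse = ", "),
              if (is.null(x$tail_type)) "-" else x$tail_type,
              if (is.null(x$tail_name)) "" else sprintf("; tail name: %s", x$tail_name),
              if (length(x$tail_predicates) == 0) "" else
                sprintf("; predicates: %s",
                        paste(vapply(x$tail_predicates, function(p)
                          sprintf("%s(%s %s)", p$aggregate, p$key, p$op), character(1)),
                          collapse = ", "))))
  invisible(x)
}

# Longest-match, non-overlapping scan of the question against the graph's
# name index. Matches respect token boundaries (the characters flanking a
# match may not be alphanumeric). Returns matched surfaces in order of
# appearance.
scan_lexicon <- function(question, kg) {
  q <- casefold(question)
  lex <- names(kg$name_index)
  lex <- lex[order(-nchar(lex), lex, method = "radix")]
  taken <- rep(FALSE, nchar(q))
  hits <- data.frame(start = integer(0), name = character(0),
                     stringsAsFactors = FALSE)
  for (nm in lex) {
    pos <- gregexpr(nm, q, fixed = TRUE)[[1]]
    if (pos[1] == -1) next
    len <- nchar(nm)
    for (p in pos) {
      end <- p + len - 1
      if (any(taken[p:end])) next
      before <- if (p > 1) substr(q, p - 1, p - 1) else " "
      after <- if (end < nchar(q)) substr(q, end + 1, end + 1) else " "
      if (grepl("[[:alnum:]]", before) || grepl("[[:alnum:]]", after)) next
      taken[p:end] <- TRUE
      hits <- rbind(hits, data.frame(start = p,
                                     name = substr(question, p, end),
                                     stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

#' Deterministic rule-based key-information extractor
#'
#' The reference extractor backend: a pure function of the question text
#' given the graph and configuration, suitable as an offline stand-in for an
#' LLM extractor. It (1) finds head entity names by a longest-match lexicon
#' scan against the graph's name index, so every emitted name is a verbatim
#' substring of the question; (2) reads the sought tail type off
#' interrogative phrases (`interrogative_map`); (3) turns attribute cue
#' phrases into tail predicates; and (4) assigns the reasoning category: two
#' or more heads make an intersection question, tail predicates make an
#' attribute question, otherwise the question is one-hop when head and tail
#' types are adjacent on the schema graph and multihop when they are not.
#'
#' @param kg A `kgqa_kg` (supplies the name lexicon and schema adjacency).
#' @param config Configuration list, see [default_config()].
#' @return A function `question -> kgqa_frame` usable as the `backend` of
#'   [extract_key_info()].
#' @export
rule_extractor <- function(kg, config = default_config()) {
  schema <- build_schema_graph(kg)
  force(config)
  function(question) {
    stopifnot(is.character(question), length(question) == 1)
    if (!nzchar(trimws(question))) stop_extraction_failure(question, "empty question")
    hits <- scan_lexicon(question, kg)
    if (nrow(hits) == 0) stop_extraction_failure(question)
    ql <- casefold(question)

    tail_type <- NULL
    phrases <- names(config$interrogative_map)
    for (ph in phrases[order(-nchar(phrases), method = "radix")]) {
      if (grepl(ph, ql, fixed = TRUE)) {
        tail_type <- unname(config$interrogative_map[[ph]])
        break
      }
    }

    preds <- list()
    for (cue in config$attribute_cues) {
      if (grepl(cue$phrase, ql, fixed = TRUE)) {
        preds[[length(preds) + 1]] <-
          attr_predicate(cue$key, op = cue$op,
                         aggregate = if (is.null(cue$aggregate)) "none" else cue$aggregate)
      }
    }

    relational <- any(vapply(config$relation_cues,
                             function(rx) grepl(rx, ql), logical(1)))
    tail_name <- NULL
    heads <- hits$name
    if (relational && nrow(hits) >= 2) {
      heads <- hits$name[1]
      tail_name <- hits$name[2]
      tt <- resolve_entity(kg, tail_name)
      if (nrow(tt) > 0) tail_type <- tt$etype[1]
    }

    if (length(heads) >= 2) {
      category <- "intersection"
    } else if (length(preds) > 0) {
      category <- "attribute"
    } else {
      h <- resolve_entity(kg, heads[1])
      category <- "multihop"
      if (nrow(h) > 0 && !is.null(tail_type)) {
        if (identical(h$etype[1], tail_type) ||
            types_adjacent(schema, h$etype[1], tail_type))
          category <- "one-hop"
      }
    }

    question_frame(question, heads, tail_type = tail_type,
                   tail_name = tail_name, tail_predicates = preds,
                   category = category)
  }
}

#' Wrap an LLM completion function as an extractor backend
#'
#' Adapter for model-based extraction: `complete` maps a prompt string to a
#' model response which must be a JSON object with fields `heads` (array of
#' strings) and optionally `tail_type`, `tail_name`, `category`. The prompt
#' template ships in `inst/prompts/extract_key_info.txt`. A malformed
#' response is retried once, then rejected. Model-backed extraction is not
#' deterministic and is never used in tests.
#'
#' @param complete Function `prompt -> character(1)`.
#' @return A function `question -> kgqa_frame`.
#' @export
llm_extractor <- function(complete) {
  template <- paste(readLines(system.file("prompts", "extract_key_info.txt",
                                          package = "kgqa"), warn = FALSE),
                    collapse = "\n")
  function(question) {
    prompt <- sub("{question}", question, template, fixed = TRUE)
    for (attempt in 1:2) {
      out <- try(jsonlite::fromJSON(complete(prompt), simplifyVector = TRUE),
                 silent = TRUE)
      if (!inherits(out, "try-error") && !is.null(out$heads) &&
          length(out$heads) >= 1) {
        cat_ <- if (is.null(out$category)) {
          if (length(out$heads) >= 2) "intersection" else "one-hop"
        } else out$category
        return(question_frame(question, out$heads,
                              tail_type = out$tail_type,
                              tail_name = out$tail_name,
                              category = cat_))
      }
    }
    stop_extraction_failure(question, "model response not parseable")
  }
}

#' Extract key information from a question
#'
#' Runs an extractor backend and validates the result: the frame must carry
#' at least one head entity name and exactly one reasoning category.
#'
#' @param question Question text (non-empty).
#' @param backend A function `question -> kgqa_frame`, e.g. from
#'   [rule_extractor()].
#' @return A `kgqa_frame`.
#' @export
extract_key_info <- function(question, backend) {
  frame <- backend(question)
  if (!inherits(frame, "kgqa_frame")) stop_config_error("backend did not return a frame")
  if (nrow(frame$heads) < 1) stop_extraction_failure(question)
  frame
}

#' Resolve head entity types against the graph
#'
#' Each head name is looked up with [resolve_entity()]; the matching entity
#' type fills the frame's head type slot. Lookup is exact, so a head
#' misspelled by even one letter raises `kgqa_entity_not_found` naming the
#' offending string -- no fuzzy recovery is attempted.
#'
#' @param kg A `kgqa_kg`.
#' @param frame A `kgqa_frame` from [extract_key_info()].
#' @return The frame with head types filled in (order preserved). When a
#'   known tail name is present, its type fills `tail_type` as well.
#' @export
resolve_head_types <- function(kg, frame) {
  stopifnot(inherits(frame, "kgqa_frame"))
  for (i in seq_len(nrow(frame$heads))) {
    ents <- resolve_entity(kg, frame$heads$name[i])
    if (nrow(ents) == 0) stop_entity_not_found(frame$heads$name[i])
    frame$heads$etype[i] <- ents$etype[1]
  }
  if (!is.null(frame$tail_name)) {
    ents <- resolve_entity(kg, frame$tail_name)
    if (nrow(ents) == 0) stop_entity_not_found(frame$tail_name)
    if (is.null(frame$tail_type)) frame$tail_type <- ents$etype[1]
  }
  frame
}
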