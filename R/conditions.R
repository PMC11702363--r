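#' Structured error conditions
#'
#' All pipeline failures are signalled as classed conditions so callers (and
#' the command-line wrapper) can distinguish them: `kgqa_entity_not_found`
#' (a head entity name has no exact match in the graph),
#' `kgqa_no_path` (head and tail entity types are disconnected on the schema
#' graph), `kgqa_extraction_failure` (the extractor found no head entity in
#' the question), `kgqa_load_error` (malformed node/edge tables),
#' `kgqa_config_error` (invalid configuration or arguments) and
#' `kgqa_degenerate_embedding` (zero vector where the embedder contract
#' forbids one). Every class also inherits from `kgqa_error`.
#'
#' @param message Human-readable description.
#' @param class Condition subclass.
#' @param ... Named condition fields (e.g. `name`, `question`).
#' @return Never returns; throws the condition.
#' @keywords internal
kgqa_stop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "kgqa_error")))
}

stop_entity_not_found <- function(name) {
  kgqa_stop("kgqa_entity_not_found",
            sprintf("entity not found in the knowledge graph: \"%s\"", name),
            name = name)
}

stop_no_path <- function(head_type, tail_type) {
  kgqa_stop("kgqa_no_path",
            sprintf("no relational path on the schema graph from type \"%s\" to type \"%s\"",
                    head_type, tail_type),
            head_type = head_type, tail_type = tail_type)
}

stop_extraction_failure <- function(question, reason = "no head entity recognized") {
  kgqa_stop("kgqa_extraction_failure",
            sprintf("could not extract key information (%s) from question: %s",
                    reason, question),
            question = question)
}

stop_load_error <- function(message, ...) {
  kgqa_stop("kgqa_load_error", message, ...)
}

stop_config_error <- function(message, ...) {
  kgqa_stop("kgqa_config_error", message, ...)
}
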