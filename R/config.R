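#' Default pipeline configuration
#'
#' Bundles the knobs of the deterministic reference backends:
#'
#' * `embedder_dim` -- dimension of the bag-of-tokens hashing embedder.
#' * `interrogative_map` -- phrases that reveal the sought tail entity type
#'   ("what types of cancer" asks for a `disease`, "which drugs" for a
#'   `drug`, ...). Scanned longest phrase first.
#' * `attribute_cues` -- phrases that introduce tail attribute constraints;
#'   each cue carries the attribute key, the predicate operator and an
#'   optional aggregate ("maximum age" asks for the `max` of `maximum_age`).
#' * `relation_cues` -- regular expressions marking relation-seeking
#'   questions ("what is the relationship between X and Y"), where the second
#'   recognized entity is a known tail entity rather than a second head.
#' * `no_answer_text` -- emitted verbatim when the answer set is empty; the
#'   composer never fabricates an answer.
#'
#' A YAML file with any subset of these fields can override the defaults via
#' [load_config()].
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    embedder_dim = 256L,
    no_answer_text = "No answer was found in the knowledge graph.",
    interrogative_map = c(
      "what types of cancer"   = "disease",
      "what type of cancer"    = "disease",
      "what cancers"           = "disease",
      "what diseases"          = "disease",
      "which diseases"         = "disease",
      "what disease"           = "disease",
      "which disease"          = "disease",
      "what genetic mutations" = "mutation",
      "what mutations"         = "mutation",
      "which mutations"        = "mutation",
      "which mutation"         = "mutation",
      "which drugs"            = "drug",
      "what drugs"             = "drug",
      "which drug"             = "drug",
      "what drug"              = "drug",
      "which genes"            = "gene",
      "what genes"             = "gene",
      "which gene"             = "gene",
      "what gene"              = "gene",
      "clinical trials"        = "clinical_trial",
      "clinical trial"         = "clinical_trial"),
    attribute_cues = list(
      list(phrase = "maximum age",      key = "maximum_age",
           op = "exists", aggregate = "max"),
      list(phrase = "minimum age",      key = "minimum_age",
           op = "exists", aggregate = "min"),
      list(phrase = "targeted therapy", key = "targeted_therapy",
           op = "exists", aggregate = "none")),
    relation_cues = c("relationship between", "relation between",
                      "how (is|are) .* related to"))
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it over [default_config()]; fields not
#' present in the file keep their defaults.
#'
#' @param path Path to a YAML file (optional; `NULL` returns the defaults).
#' @return A configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_config_error(sprintf("config file not found: %s", path))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config_error("the 'yaml' package is required to read config files")
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (!is.null(user$interrogative_map))
    cfg$interrogative_map <- unlist(user$interrogative_map)
  cfg
}
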