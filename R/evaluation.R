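#' Tokenize text for ROUGE-L scoring and hashing embeddings
#'
#' Case-folds and splits on runs of non-alphanumeric characters, dropping
#' empty tokens. No stemming and no stopword removal are applied.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize_text("ALK-p.L1196M")  # "alk" "p" "l1196m"
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- strsplit(casefold(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Length of the longest common subsequence of two token lists
#'
#' Standard dynamic program over token sequences, O(|a| x |b|) time with a
#' two-row table.
#'
#' @param a,b Character vectors of tokens.
#' @return Integer LCS length.
#' @export
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  # map tokens to integers once so the inner comparison is cheap
  vocab <- unique(c(a, b))
  ai <- match(a, vocab); bi <- match(b, vocab)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (ai[i] == bi[j]) prev[j] + 1L else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' ROUGE-L recall, precision and F1
#'
#' With `L` the longest-common-subsequence length between the tokenized
#' candidate and reference: recall `R = L / |ref|`, precision
#' `P = L / |cand|`, and the balanced F-measure `F1 = 2PR / (P + R)` (0 when
#' `P + R = 0`). An empty candidate scores (0, 0, 0); an empty reference is
#' an error.
#'
#' @param candidate,reference Texts to compare.
#' @return Named numeric vector `recall`, `precision`, `f1`, all in `[0, 1]`.
#' @export
#' @examples
#' rouge_l("the cat sat", "the cat sat on the mat")
rouge_l <- function(candidate, reference) {
  ref <- tokenize_text(reference)
  if (length(ref) == 0)
    stop_config_error("ROUGE-L reference must be non-empty after tokenization")
  cand <- tokenize_text(candidate)
  if (length(cand) == 0)
    return(c(recall = 0, precision = 0, f1 = 0))
  l <- lcs_length(cand, ref)
  r <- l / length(ref)
  p <- l / length(cand)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(recall = r, precision = p, f1 = f)
}

# Best score over multiple admissible references (gold answers can be
# verbalized more than one way); the reference with the highest F1 wins.
rouge_l_multi <- function(candidate, references) {
  scores <- lapply(references, function(ref) rouge_l(candidate, ref))
  scores[[which.max(vapply(scores, `[[`, numeric(1), "f1"))]]
}

#' Score predictions against a gold benchmark
#'
#' Per item: ROUGE-L of the predicted answer text against the gold answer
#' text (maximum F1 over multiple gold texts if several are given) and an
#' exact-set-match flag (predicted answer set equals the gold set after
#' [normalize_name()]). Macro metrics are plain arithmetic means over items.
#' A gold item with no matching prediction is scored as zeros with a
#' warning.
#'
#' @param predictions List of lists with fields `id`, `text`, `answer_set`.
#' @param gold_items List of benchmark items with fields `id`,
#'   `gold_answer_text`, `gold_answer_set` (see [generate_benchmark()] /
#'   [read_benchmark()]).
#' @return An object of class `kgqa_eval_report`: `per_item` data.frame and
#'   `macro` list (`rouge_recall`, `rouge_precision`, `rouge_f1`,
#'   `exact_set_match`).
#' @export
evaluate_benchmark <- function(predictions, gold_items) {
  if (length(gold_items) == 0) stop_config_error("empty benchmark")
  pred_ids <- vapply(predictions, `[[`, character(1), "id")
  rows <- lapply(gold_items, function(g) {
    i <- match(g$id, pred_ids)
    if (is.na(i)) {
      warning(sprintf("no prediction for benchmark item %s; scored as zeros", g$id))
      return(data.frame(id = g$id, rouge_recall = 0, rouge_precision = 0,
                        rouge_f1 = 0, exact_set_match = FALSE,
                        stringsAsFactors = FALSE))
    }
    p <- predictions[[i]]
    sc <- rouge_l_multi(p$text, as.character(g$gold_answer_text))
    em <- setequal(normalize_name(as.character(p$answer_set)),
                   normalize_name(as.character(g$gold_answer_set)))
    data.frame(id = g$id, rouge_recall = sc[["recall"]],
               rouge_precision = sc[["precision"]], rouge_f1 = sc[["f1"]],
               exact_set_match = em, stringsAsFactors = FALSE)
  })
  per_item <- do.call(rbind, rows)
  macro <- list(rouge_recall = mean(per_item$rouge_recall),
                rouge_precision = mean(per_item$rouge_precision),
                rouge_f1 = mean(per_item$rouge_f1),
                exact_set_match = mean(per_item$exact_set_match))
  structure(list(per_item = per_item, macro = macro), class = "kgqa_eval_report")
}

#' @export
print.kgqa_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<kgqa evaluation: %d items> macro ROUGE-L F1 = %.3f, ",
                     "exact set match = %.3f\n"),
              nrow(x$per_item), x$macro$rouge_f1, x$macro$exact_set_match))
  invisible(x)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report A `kgqa_eval_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_item, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_item = report$per_item, macro = report$macro),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Pluggable semantic scorers
#'
#' External semantic metrics (model-judged similarity, contextual-embedding
#' F1) are exposed behind one interface: a scorer is any function
#' `(candidate, reference) -> numeric in [0, 1]`. [apply_scorer()] maps a
#' scorer over prediction/gold pairs; no network-backed scorer ships with
#' the package and none is used in its tests.
#'
#' @param scorer A function `(candidate, reference) -> numeric(1)`.
#' @param predictions,gold_items As in [evaluate_benchmark()].
#' @return Numeric vector of scores aligned with `gold_items`.
#' @export
apply_scorer <- function(scorer, predictions, gold_items) {
  pred_ids <- vapply(predictions, `[[`, character(1), "id")
  vapply(gold_items, function(g) {
    i <- match(g$id, pred_ids)
    if (is.na(i)) return(0)
    scorer(predictions[[i]]$text, as.character(g$gold_answer_text)[1])
  }, numeric(1))
}
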