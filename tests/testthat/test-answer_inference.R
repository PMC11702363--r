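trial_fixture <- function() {
  kg <- toy_oncology_kg()
  frame <- resolve_head_types(kg, question_frame(
    "max age?", "meningioma", tail_type = "clinical_trial",
    tail_predicates = list(attr_predicate("maximum_age", "exists", aggregate = "max")),
    category = "attribute"))
  op <- rel_path(c("disease", "clinical_trial"), "has_trial")
  sg <- execute_query(kg, generate_query(frame, op))
  list(kg = kg, frame = frame, op = op, sg = sg)
}

test_that("pruning drops chains that violate the head, path or predicates", {
  kg <- toy_oncology_kg()
  f <- resolve_head_types(kg, question_frame("q", "gefitinib", tail_type = "disease"))
  op <- rel_path(c("drug", "disease"), "treats")
  q <- generate_query(f, op)
  sg <- execute_query(kg, q)
  # inject a chain anchored at a different drug: criterion (a) removes it
  alien <- execute_query(kg, graph_query("drug", "crizotinib",
                                         data.frame(label = "treats",
                                                    type = "disease")))
  mixed <- structure(list(chains = c(sg$chains, alien$chains),
                          entity_attributes = c(sg$entity_attributes,
                                                alien$entity_attributes)),
                     class = "kgqa_subgraph")
  pr <- prune_chains(mixed, f, op)
  expect_true(all(vapply(pr$chains, function(ch) ch$entity_names[1] == "gefitinib",
                         logical(1))))
  expect_lt(length(pr$chains), length(mixed$chains))

  # a chain whose labels deviate from the optimal path: criterion (b)
  wrong_op <- rel_path(c("drug", "gene"), "inhibits")
  expect_length(prune_chains(sg, f, wrong_op)$chains, 0)

  # all-compliant subgraphs pass through unchanged, and pruning is idempotent
  expect_equal(length(prune_chains(sg, f, op)$chains), length(sg$chains))
  once <- prune_chains(mixed, f, op)
  twice <- prune_chains(once, f, op)
  expect_identical(vapply(twice$chains, function(c) paste(c$entity_ids, collapse = "|"),
                          character(1)),
                   vapply(once$chains, function(c) paste(c$entity_ids, collapse = "|"),
                          character(1)))
})

test_that("a max aggregate keeps only the arg-maximum trial of {65, 80, 75}", {
  fx <- trial_fixture()
  expect_length(fx$sg$chains, 3)
  pr <- prune_chains(fx$sg, fx$frame, fx$op)
  expect_length(pr$chains, 1)
  expect_equal(chain_terminal_name(pr$chains[[1]]), "NCT0000002")
  aset <- derive_answer_set(pr, generate_query(fx$frame, fx$op))
  expect_equal(aset$items, "80")
})

test_that("answer derivation projects terminals, labels and attributes", {
  kg <- toy_oncology_kg()
  f <- resolve_head_types(kg, question_frame("q", "diethylstilbestrol",
                                             tail_type = "disease"))
  op <- rel_path(c("drug", "disease"), "treats")
  q <- generate_query(f, op)
  aset <- derive_answer_set(prune_chains(execute_query(kg, q), f, op), q)
  expect_equal(aset$items,
               sort(c("prostate carcinoma",
                      "basaloid large cell carcinoma of the lung")))
  expect_true(all(lengths(aset$provenance) >= 1))

  fr <- resolve_head_types(kg, question_frame("q", "diethylstilbestrol",
                                              tail_name = "prostate carcinoma"))
  qr <- generate_query(fr, op)
  asr <- derive_answer_set(prune_chains(execute_query(kg, qr), fr, op), qr)
  expect_equal(asr$items, "treats")

  # derive(prune(S)) is a subset of derive(S)
  full <- derive_answer_set(execute_query(kg, q), q)
  expect_true(all(aset$items %in% full$items))
})

test_that("chains verbalize in stored orientation with de-underscored labels", {
  kg <- tiny_kg()
  sg <- execute_query(kg, graph_query("drug", "carteolol",
                                      data.frame(label = "inhibits", type = "gene")))
  expect_equal(chain_to_sentence(sg$chains[[1]]), "carteolol inhibits ADRB1")

  kg2 <- toy_oncology_kg()
  sg2 <- execute_query(kg2, graph_query(
    "disease", "basaloid large cell carcinoma of the lung",
    data.frame(label = c("has_mutation", "of_gene"),
               type = c("mutation", "gene"))))
  s <- chain_to_sentence(sg2$chains[[1]])
  expect_equal(lengths(regmatches(s, gregexpr(", and ", s, fixed = TRUE))), 1)
  expect_match(s, "has mutation")
  expect_match(s, "of gene")

  bare <- execute_query(kg, graph_query("drug", "carteolol"))
  expect_error(chain_to_sentence(bare$chains[[1]]), class = "kgqa_config_error")
})

test_that("the composer grounds every item, exactly once in the summary", {
  aset <- answer_set("propranolol")
  ans <- compose_answer("carteolol inhibits ADRB1", aset)
  summary_part <- sub(" Evidence:.*$", "", ans$text)
  expect_equal(lengths(regmatches(summary_part,
                                  gregexpr("propranolol", summary_part))), 1)

  empty <- compose_answer(character(0), answer_set(character(0)))
  expect_equal(empty$text, default_config()$no_answer_text)

  three <- compose_answer("ev", answer_set(c("a1", "b2", "c3")))
  for (it in c("a1", "b2", "c3")) expect_match(three$text, it, fixed = TRUE)

  # a model-backed composer that drops an item is rejected
  bad_backend <- function(sentences, items) "nothing relevant"
  expect_error(compose_answer("ev", aset, backend = bad_backend),
               class = "kgqa_config_error")
})

test_that("composed text never names an unsupported terminal-type entity", {
  kg <- generate_kg(default_spec())
  bench <- generate_benchmark(kg, default_spec())
  schema <- build_schema_graph(kg)
  for (it in bench[c(1, 11, 21, 31)]) {
    ans <- answer_question(kg, it$question, schema = schema)
    f <- attr(ans, "frame")
    tail_names <- kg$nodes$name[kg$nodes$etype == f$tail_type]
    supported <- c(ans$answer_set$items,
                   unlist(lapply(ans$sentences, identity)))
    for (nm in tail_names) {
      if (grepl(nm, ans$text, fixed = TRUE)) {
        in_items <- nm %in% ans$answer_set$items
        in_evidence <- any(vapply(ans$sentences, function(s)
          grepl(nm, s, fixed = TRUE), logical(1)))
        expect_true(in_items || in_evidence)
      }
    }
  }
})
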