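test_that("schema construction abstracts entities to types and keeps parallel labels", {
  expect_equal(nrow(build_schema_graph(tiny_kg())$edges), 1)
  expect_equal(build_schema_graph(tiny_kg())$types, c("drug", "gene"))

  nodes <- data.frame(id = c("d1", "d2", "s1"), name = c("a", "b", "c"),
                      etype = c("drug", "drug", "disease"))
  edges <- data.frame(head_id = c("d1", "d2", "d1"),
                      label = c("treats", "treats", "sensitive_to"),
                      tail_id = c("s1", "s1", "s1"))
  sch <- build_schema_graph(load_kg(nodes, edges))
  # two relation labels between the same type pair stay as parallel edges;
  # duplicate instances of one label collapse
  expect_equal(nrow(sch$edges), 2)
  expect_setequal(sch$edges$label, c("treats", "sensitive_to"))
})

test_that("identical endpoints give the single zero-hop path", {
  sch <- build_schema_graph(toy_oncology_kg())
  ps <- candidate_paths(sch, "drug", "drug")
  expect_length(ps, 1)
  expect_equal(ps[[1]]$types, "drug")
  expect_equal(ps[[1]]$length, 0)
})

test_that("a chain schema yields exactly the forced path; parallel labels fan out", {
  nodes <- data.frame(id = c("d", "s", "g"), name = c("x", "y", "z"),
                      etype = c("drug", "disease", "gene"))
  edges <- data.frame(head_id = c("d", "s"),
                      label = c("treats", "has_mutation"),
                      tail_id = c("s", "g"))
  sch <- build_schema_graph(load_kg(nodes, edges))
  ps <- candidate_paths(sch, "drug", "gene")
  expect_length(ps, 1)
  expect_equal(verbalize_path(ps[[1]]), "drug treats disease has mutation gene")

  edges2 <- rbind(edges[1, ], data.frame(head_id = "d", label = "sensitive_to",
                                         tail_id = "s"))
  sch2 <- build_schema_graph(load_kg(nodes, edges2))
  ps2 <- candidate_paths(sch2, "drug", "disease")
  expect_length(ps2, 2)
  expect_setequal(vapply(ps2, verbalize_path, character(1)),
                  c("drug treats disease", "drug sensitive to disease"))

  expect_length(candidate_paths(sch2, "gene", "drug"), 0)  # gene now isolated
  expect_error(candidate_paths(sch, "drug", "protein"),
               class = "kgqa_unknown_type")
})

test_that("BFS path enumeration equals exhaustive DFS on random schema multigraphs", {
  set.seed(202)
  for (rep in 1:50) {
    sch <- rand_schema()
    h <- sample(sch$types, 1)
    t <- sample(sch$types, 1)
    got <- sort(vapply(candidate_paths(sch, h, t), verbalize_path, character(1)),
                method = "radix")
    expect_identical(got, dfs_shortest_verbalized(sch, h, t))
  }
})

test_that("all returned paths share the minimal length and never repeat a type", {
  set.seed(203)
  for (rep in 1:30) {
    sch <- rand_schema()
    h <- sample(sch$types, 1)
    t <- sample(sch$types, 1)
    ps <- candidate_paths(sch, h, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, function(p) p$length, numeric(1))
    expect_true(all(lens == lens[1]))
    for (p in ps) expect_false(anyDuplicated(p$types) > 0)
  }
})

test_that("path verbalization renders types and labels in order, de-underscored", {
  expect_equal(verbalize_path(rel_path("drug")), "drug")
  expect_equal(verbalize_path(rel_path(c("drug", "disease"), "treats")),
               "drug treats disease")
  expect_equal(
    verbalize_path(rel_path(c("disease", "mutation", "gene"),
                            c("has_mutation", "of_gene"))),
    "disease has mutation mutation of gene gene")
})

test_that("cosine similarity matches hand-evaluated cases and its contract", {
  expect_equal(cosine_similarity(c(1, 2, 2), c(1, 2, 2)), 1, tolerance = 1e-15)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9,
               tolerance = 1e-15)
  set.seed(7)
  for (i in 1:20) {
    u <- rnorm(16); v <- rnorm(16); a <- runif(1, 0.01, 100)
    s <- cosine_similarity(u, v)
    expect_equal(cosine_similarity(v, u), s)
    expect_true(s >= -1 - 1e-12 && s <= 1 + 1e-12)
    expect_lt(abs(cosine_similarity(a * u, v) - s), 1e-12)
  }
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)),
               class = "kgqa_config_error")
  expect_error(cosine_similarity(c(0, 0), c(1, 2)),
               class = "kgqa_degenerate_embedding")
})

test_that("the hashing embedder is deterministic, bag-of-tokens and fixed-dimension", {
  emb <- hash_embedder(256)
  expect_identical(emb("drug treats disease"), emb("drug treats disease"))
  expect_identical(emb("drug treats disease"), emb("disease treats drug"))
  expect_length(emb("anything at all"), 256)
  expect_equal(sqrt(sum(emb("a b c")^2)), 1, tolerance = 1e-12)
  expect_error(emb(""), class = "kgqa_degenerate_embedding")
  expect_error(emb("   ...   "), class = "kgqa_degenerate_embedding")
  # alternative backends keep the contract but change the vectors
  emb64 <- hash_embedder(64)
  expect_length(emb64("drug"), 64)
})

test_that("optimal-path selection is an argmax with a stable lexicographic tie-break", {
  emb <- hash_embedder(256)
  single <- list(rel_path(c("drug", "disease"), "treats"))
  expect_equal(select_optimal_path("anything", single, emb), single[[1]],
               ignore_attr = TRUE)

  cands <- list(
    rel_path(c("disease", "mutation", "gene"), c("has_mutation", "of_gene")),
    rel_path(c("disease", "drug", "gene"), c("treats", "inhibits")))
  q <- "Which gene has a mutation present in meningioma?"
  # brute-force rescoring oracle
  scores <- vapply(cands, function(p)
    cosine_similarity(emb(q), emb(verbalize_path(p))), numeric(1))
  best <- cands[[which.max(scores)]]
  expect_equal(verbalize_path(select_optimal_path(q, cands, emb)),
               verbalize_path(best))
  expect_equal(verbalize_path(best), "disease has mutation mutation of gene gene")

  # order invariance
  expect_equal(verbalize_path(select_optimal_path(q, rev(cands), emb)),
               verbalize_path(select_optimal_path(q, cands, emb)))

  # exact ties break to the lexicographically smallest verbalization
  tied <- list(rel_path(c("drug", "disease"), "zz_rel"),
               rel_path(c("drug", "disease"), "aa_rel"))
  sel <- select_optimal_path("completely unrelated words here", tied, emb)
  expect_equal(verbalize_path(sel), "drug aa rel disease")
  expect_error(select_optimal_path("q", list(), emb), class = "kgqa_no_path")
})

test_that("selection equals exhaustive scoring on random candidate sets", {
  emb <- hash_embedder(128)
  set.seed(301)
  words <- c("drug", "gene", "disease", "mutation", "trial", "treats",
             "inhibits", "resistant", "sensitive", "alpha", "beta", "gamma")
  for (rep in 1:40) {
    cands <- lapply(seq_len(sample(2:6, 1)), function(i) {
      k <- sample(2:4, 1)
      rel_path(sample(words, k, replace = FALSE),
               sample(words, k - 1, replace = TRUE))
    })
    q <- paste(sample(words, 5, replace = TRUE), collapse = " ")
    verb <- vapply(cands, verbalize_path, character(1))
    scores <- vapply(verb, function(tx) cosine_similarity(emb(q), emb(tx)),
                     numeric(1))
    top <- max(scores)
    expected <- sort(verb[scores >= top - 1e-12], method = "radix")[1]
    expect_equal(verbalize_path(select_optimal_path(q, cands, emb)), expected)
  }
})
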