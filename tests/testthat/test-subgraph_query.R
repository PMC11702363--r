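resolved_frame <- function(kg, ...) resolve_head_types(kg, question_frame(...))

test_that("query generation maps frame and path onto anchor, hops and projection", {
  kg <- toy_oncology_kg()
  f <- resolved_frame(kg, "q", "diethylstilbestrol", tail_type = "disease")
  op <- rel_path(c("drug", "disease"), "treats")
  q <- generate_query(f, op)
  expect_equal(q$anchor_type, "drug")
  expect_equal(q$anchor_name, "diethylstilbestrol")
  expect_equal(q$hops$label, "treats")
  expect_equal(q$hops$type, "disease")
  expect_equal(q$return_spec, "terminal-entities")

  fa <- resolved_frame(kg, "q", "meningioma", tail_type = "clinical_trial",
                       tail_predicates = list(attr_predicate("maximum_age", "exists",
                                                             aggregate = "max")),
                       category = "attribute")
  qa <- generate_query(fa, rel_path(c("disease", "clinical_trial"), "has_trial"))
  expect_equal(qa$return_spec, "terminal-attributes")
  expect_equal(qa$predicates[[1]]$aggregate, "max")

  # zero-hop attribute query on the head itself
  fz <- resolved_frame(kg, "q", "diethylstilbestrol",
                       tail_predicates = list(attr_predicate("targeted_therapy", "exists")),
                       category = "attribute")
  qz <- generate_query(fz, rel_path("drug"))
  expect_equal(nrow(qz$hops), 0)
  expect_equal(qz$return_spec, "terminal-attributes")

  # known tail entity: relation-labels projection
  fr <- resolved_frame(kg, "q", "diethylstilbestrol",
                       tail_name = "prostate carcinoma")
  qr <- generate_query(fr, rel_path(c("drug", "disease"), "treats"))
  expect_equal(qr$return_spec, "relation-labels")
  expect_equal(qr$predicates[[1]]$key, "name")

  # path/head type mismatch is rejected
  expect_error(generate_query(f, rel_path(c("gene", "drug"), "inhibits")),
               class = "kgqa_config_error")
})

test_that("canonical Cypher rendering matches the grammar", {
  q <- graph_query("drug", "diethylstilbestrol",
                   data.frame(label = "treats", type = "disease"))
  expect_identical(render_cypher(q),
    'MATCH (a:drug {name: "diethylstilbestrol"})-[:treats]-(x1:disease) RETURN x1.name')

  qz <- graph_query("drug", "carteolol",
                    predicates = list(attr_predicate("targeted_therapy", "exists")),
                    return_spec = "terminal-attributes")
  expect_identical(render_cypher(qz),
    'MATCH (a:drug {name: "carteolol"}) RETURN a.targeted_therapy')

  qw <- graph_query("disease", "meningioma",
                    data.frame(label = "has_trial", type = "clinical_trial"),
                    list(attr_predicate("maximum_age", "ge", 70)))
  expect_identical(render_cypher(qw),
    paste0('MATCH (a:disease {name: "meningioma"})-[:has_trial]-',
           '(x1:clinical_trial) WHERE x1.maximum_age >= 70 RETURN x1.name'))

  qr <- graph_query("drug", "diethylstilbestrol",
                    data.frame(label = "treats", type = "disease"),
                    list(attr_predicate("name", "equals", "prostate carcinoma")),
                    "relation-labels")
  expect_identical(render_cypher(qr),
    paste0('MATCH (a:drug {name: "diethylstilbestrol"})-[r1:treats]-',
           '(x1:disease) WHERE x1.name = "prostate carcinoma" RETURN type(r1)'))

  # strings with quotes and backslashes survive escaping
  qq <- graph_query("drug", 'we"ird\\name')
  expect_identical(render_cypher(qq),
                   'MATCH (a:drug {name: "we\\"ird\\\\name"}) RETURN a.name')
})

test_that("render -> parse -> render is the identity on random queries", {
  set.seed(404)
  for (rep in 1:100) {
    q <- rand_query()
    txt <- render_cypher(q)
    q2 <- parse_cypher(txt)
    expect_identical(render_cypher(q2), txt)
    expect_identical(q2$anchor_name, q$anchor_name)
    expect_identical(q2$hops$label, q$hops$label)
    expect_identical(q2$return_spec, q$return_spec)
  }
  expect_error(parse_cypher("SELECT * FROM graph"), class = "kgqa_config_error")
})

test_that("retrieval yields one subgraph per head with the frame's terminal type", {
  kg <- toy_oncology_kg()
  f <- resolved_frame(kg, "q", "diethylstilbestrol", tail_type = "disease")
  sgs <- run_retrieval(kg, f, rel_path(c("drug", "disease"), "treats"))
  expect_length(sgs, 1)
  expect_length(sgs[[1]]$chains, 2)  # treats prostate carcinoma + basaloid ...
  for (ch in sgs[[1]]$chains)
    expect_equal(ch$entity_types[length(ch$entity_types)], f$tail_type)

  f2 <- resolved_frame(kg, "q", c("ALK", "basaloid large cell carcinoma of the lung"),
                       tail_type = "drug", category = "intersection")
  sgs2 <- run_retrieval(kg, f2, list(rel_path(c("gene", "drug"), "inhibits"),
                                     rel_path(c("disease", "drug"), "treats")))
  expect_length(sgs2, 2)
  expect_s3_class(attr(sgs2[[1]], "query"), "kgqa_query")
})

test_that("answer-set intersection behaves like set intersection with merged provenance", {
  a <- answer_set(c("gefitinib", "crizotinib"))
  b <- answer_set(c("crizotinib", "erlotinib"))
  expect_equal(intersect_answers(list(a, b))$items, "crizotinib")
  expect_equal(intersect_answers(list(a, a))$items, sort(a$items))
  expect_equal(intersect_answers(list(a, answer_set(character(0))))$items,
               character(0))
})

test_that("intersection is commutative, associative and idempotent on random sets", {
  set.seed(505)
  pool <- paste0("drug", 1:8)
  for (rep in 1:100) {
    x <- answer_set(sample(pool, sample(0:5, 1)))
    y <- answer_set(sample(pool, sample(0:5, 1)))
    z <- answer_set(sample(pool, sample(0:5, 1)))
    expect_identical(intersect_answers(list(x, y))$items,
                     intersect_answers(list(y, x))$items)
    expect_identical(
      intersect_answers(list(intersect_answers(list(x, y)), z))$items,
      intersect_answers(list(x, intersect_answers(list(y, z))))$items)
    expect_identical(intersect_answers(list(x, x))$items,
                     sort(unique(x$items), method = "radix"))
  }
})
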