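# kgqa — schema-guided question answering over biomedical knowledge graphs

Biomedical question answering over a property graph (drugs, genes,
mutations, diseases, clinical trials) often has to bridge entities the
question never names: "Which gene has a mutation present in Koko adenoma?"
states a head entity and the sought tail *type*, but not the mutation in
between. `kgqa` answers such questions by reasoning on the graph's
**schema graph** — the undirected multigraph of entity types and relation
labels — instead of on the instance graph directly:

1. **Question analysis** — decompose the question into a frame: head
   entity names *Hₙ*, tail type *Tₜ*, tail attribute predicates *Tₐ*, and
   a reasoning category (one-hop, multihop, intersection, attribute).
   Head types *Hₜ* resolve by exact name lookup.
2. **Schema inference** — BFS enumerates **all** shortest relational paths
   *SP* from *Hₜ* to *Tₜ* on the schema graph (parallel relation labels
   fan out into separate candidates); the optimal path *OP* maximizes the
   cosine similarity sim(Q, SP) = (Q·SP)/(‖Q‖‖SP‖) between embeddings of
   the question and each verbalized path.
3. **Subgraph construction** — (*Hₜ, Hₙ, Tₜ, Tₐ, OP*) map onto a linear
   query in a canonical Cypher subset, executed by the built-in engine
   (undirected traversal, simple-path chains, terminal predicates).
4. **Inference** — retrieved relational chains are pruned against the
   frame (aggregates like "maximum age" reduce to the arg-extremum), the
   answer set is projected, chains verbalize into evidence sentences, and
   the final text is composed from answer set + evidence. Empty results
   give a fixed no-answer message; the composer refuses to state answers
   without supporting chains.

Extraction, embedding and composition are pluggable backends; the shipped
defaults are deterministic (lexicon rules, token-hash embedding, template
composition) so everything runs and tests offline. Adapters for
model-backed extraction/composition and for live Cypher endpoints are
contract-checked seams. A seeded generator produces an oncology-flavoured
synthetic graph plus a four-category benchmark whose gold answers come
from an independent traversal oracle, and `evaluate_benchmark()` scores
predictions by ROUGE-L (longest common subsequence recall/precision/F1)
and exact set match.

## Worked example

```r
library(kgqa)

spec  <- fixture_spec(seed = 42)          # 72 entities, ~120 relations
kg    <- generate_kg(spec)
bench <- generate_benchmark(kg, spec)     # 40 questions, 10 per category

it <- bench[[31]]
it$question
#> What is the maximum age for recruitment of clinical trials for patients
#> with Sune carcinoma?

ans <- answer_question(kg, it$question)
attr(ans, "optimal_paths")
#> [1] "disease has trial clinical trial"
attr(ans, "cypher")
#> [1] "MATCH (a:disease {name: \"Sune carcinoma\"})-[:has_trial]-(x1:clinical_trial) RETURN x1.maximum_age"
ans$text
#> Answer: 90. Evidence: Sune carcinoma has trial NCT4015373, and
#> NCT4015373 maximum age is 90.
```

The selected path reads: anchor at the disease, follow `has_trial` to
clinical trials; the `max(maximum_age)` predicate extracted from the
question prunes the trials to the arg-maximum, so the answer set is the
attribute value `90` and the evidence names the supporting trial. A
multihop question walks two hops through the unstated intermediate:

```r
a2 <- answer_question(kg, bench[[11]]$question)  # "Which gene has a mutation present in Koko adenoma?"
a2$text
#> Answer: HWF1, YUK16. Evidence: Koko adenoma has mutation HWF1 p.Z694V,
#> and HWF1 p.Z694V of gene HWF1. Koko adenoma has mutation YUK16 p.Q27E,
#> and YUK16 p.Q27E of gene YUK16.

run_benchmark(kg, bench)$macro
#> $rouge_recall [1] 1  $rouge_precision [1] 1  $rouge_f1 [1] 1  $exact_set_match [1] 1
```

Exact-match entity linking is deliberate: misspell a head entity by one
character and the pipeline raises `kgqa_entity_not_found` (or
`kgqa_extraction_failure` if nothing matches at all) rather than
fabricating an answer.

A thin command-line wrapper ships in `inst/cli/kgqa.R`
(`ask` / `bench` / `fixtures` subcommands; exit codes 2 = entity not
found, 3 = no path, 4 = extraction failure, 5 = config error).

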