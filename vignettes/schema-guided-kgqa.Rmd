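---
title: "Schema-guided question answering over biomedical knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-guided question answering over biomedical knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgqa)
```

## The problem and the model

Answering a natural-language question against a property graph -- say, a
pan-cancer graph of drugs, genes, mutations, diseases and clinical trials --
fails in a characteristic way when the question does not name the
intermediate entities. "Which gene has a mutation present in X?" gives a
head entity (the disease X) and a sought tail *type* (gene), but nothing
about the mutation in between, so retrieval keyed directly on the question
text has nothing to anchor the middle of the pattern on. The idea this
package implements is to do that reasoning one level up, on the *schema
graph*: the undirected multigraph whose nodes are entity types and whose
edges are the relation labels observed between them. Type-level paths are
few, so the missing intermediate types can be recovered by search rather
than guessed.

A knowledge graph here is a set of triplets $(e_1, r, e_2)$ over entities
$E$ and relations $R$, enriched with attribute pairs $(e, \mathit{attr})$.
A *relational path* is the type-level object $t_1\,r_1\,t_2\,r_2\cdots t_k$;
a *relational chain* is an instance-level walk matching such a path. The
pipeline is:

1. **Question analysis.** An extractor decomposes the question into a frame:
   head entity name(s) $H_n$, tail entity type $T_t$, tail attribute
   predicates $T_a$, and a reasoning category. Head types $H_t$ are then
   resolved by *exact* name lookup in the graph.
2. **Schema inference.** Breadth-first search on the schema graph
   enumerates **all** shortest relational paths from $H_t$ to $T_t$
   (layered BFS with multi-parent tracking; each minimal node sequence is
   expanded once per combination of parallel relation labels). Each
   candidate $SP$ is verbalized and scored against the question $Q$ by
   cosine similarity of embeddings,
   $\mathrm{sim}(Q, SP) = \frac{Q \cdot SP}{\lVert Q\rVert\,\lVert SP\rVert}$,
   and the argmax is the optimal path $OP$.
3. **Subgraph construction.** $(H_t, H_n, T_t, T_a, OP)$ maps
   deterministically onto a linear query in a small canonical Cypher
   subset, which the built-in engine executes: undirected traversal,
   simple-path semantics, terminal predicates applied.
4. **Inference.** Retrieved chains are pruned against the frame (anchor,
   path conformance, predicates; aggregates reduce to the arg-extremum),
   the answer set is projected per the question category, each surviving
   chain is verbalized as a sentence, and the final text is composed from
   the answer set plus that evidence. An empty set yields a fixed
   no-answer message, never an invented answer.

Four question categories are supported, mirroring the usual taxonomy of
biomedical KGQA benchmarks: **one-hop** ($H_1 + R_1 \to T_?$, and the
relation-seeking variant $H_1 + T_1 \to R_?$), **multihop**
($H_1 + R_1 \to M + R_2 \to T_?$ through an intermediate $M$),
**intersection** ($T_1 \cap T_2 \to T_?$ from two heads), and
**attribute** ($H_1 \to P_{H_1}$ or $H_1 + R_1 \to P_{T_1}$).

## Deterministic backends, and what the LLM adapters would change

The original formulation of this kind of pipeline delegates extraction,
query writing and answer composition to a large language model. Those three
stages are pluggable here, and the defaults are deterministic so that every
claim in the test suite is reproducible offline:

* **Extractor** (`rule_extractor`): longest-match lexicon scan of the
  question against the graph's name index (so head names are verbatim
  substrings of the question), an interrogative-phrase map for the tail
  type, cue phrases for attribute predicates, and the category rules
  *two heads → intersection; predicates → attribute; head and tail types
  adjacent on the schema → one-hop, else multihop*. An LLM adapter
  (`llm_extractor`, prompt in `inst/prompts/`) parses a JSON frame from a
  completion function and retries once before rejecting; it is flagged
  non-deterministic and never used in tests.
* **Embedder** (`hash_embedder`): bag-of-tokens feature hashing into 256
  dimensions, L2-normalized. 256 dimensions keeps accidental token
  collisions rare at the vocabulary sizes involved while staying cheap;
  the embedder is order-insensitive by construction, which is adequate for
  ranking short verbalized paths. Sentence-embedding models can be dropped
  in as any `function(text) -> numeric` of fixed dimension.
* **Composer**: a template (`"Answer: ..."` plus per-chain evidence
  sentences). A model-backed composer is accepted only if its output
  contains every answer item verbatim -- a faithfulness gate that turns
  hallucination into a hard error instead of silent text.

## Numerical and design choices

* **All shortest paths, not one BFS tree.** A plain BFS with a global
  visited set yields a single tree and hence one path; similarity-based
  selection is only meaningful over the complete minimal set, so the
  search tracks every predecessor in the previous BFS layer and expands
  every parallel-label combination. Paths longer than minimal are never
  searched: if nothing survives, the outcome is an explicit no-path/no-answer,
  by design.
* **Exact entity linking.** Name matching trims and collapses whitespace
  and case-folds -- nothing else. A head misspelled by one character fails
  with `kgqa_entity_not_found`. This reproduces the known brittleness of
  exact-match retrieval deliberately; fuzzy linking is out of scope.
* **Undirected matching, stored direction preserved.** The schema graph is
  undirected, so query execution ignores stored edge direction while
  traversing but reports triplets in stored orientation; rendered Cypher
  patterns use undirected `-[:label]-` elements.
* **Simple-path semantics.** Chains never revisit an entity, preventing
  degenerate back-and-forth matches on undirected edges.
* **Ties and ordering.** Equal-similarity candidates (within 1e-12) break
  to the lexicographically smallest verbalization; chains sort by an
  (entity ids, labels) key; answer items sort with a locale-independent
  radix sort. Identical inputs therefore give byte-identical outputs.
* **Aggregates after retrieval.** `max`/`min` tail predicates are applied
  at the pruning stage over the retrieved terminal set, keeping the query
  engine a pure pattern matcher.
* **ROUGE-L** uses the balanced F-measure ($\beta = 1$), case-folded
  alphanumeric tokenization, no stemming and no stopword removal; with
  several admissible gold texts the best-F1 reference counts.

## The synthetic fixture generator

`generate_kg()` emulates a small oncology property graph: drugs, genes,
mutations, diseases and clinical trials joined by treats / inhibits /
has_mutation / of_gene / resistant_to / has_trial relations, with
targeted-therapy flags on drugs and recruitment-age bounds (years) on
trials. Defaults (15 drugs, 12 genes, 15 mutations, 12 diseases, 18
trials, density 0.12) give a graph of ~72 nodes and ~120 edges in which
every disease carries at least one mutation and one trial and every drug
treats and inhibits something -- the smallest shape on which all four
question categories are instantiable with ten distinct anchors each.
`generate_benchmark()` instantiates template questions and computes gold
answers with a traversal oracle that reads the edge table directly and
never touches the schema-inference or query modules, so end-to-end
agreement between pipeline and gold is a genuine check. All randomness is
seeded; identical spec and seed give byte-identical CSV/JSON fixtures.

What the generator does **not** emulate: paraphrase variety (questions come
from fixed templates keyed to the rule extractor's lexicon), ambiguous or
shared entity names, noisy attributes, schema types outside the six-edge
oncology core, and real biomedical content. A perfect score on the
synthetic benchmark therefore demonstrates that the machinery -- frame
extraction, path search and ranking, query execution, pruning,
composition, scoring -- is internally consistent, not that the pipeline
would achieve any particular accuracy on real questions with a learned
extractor.

## Problem sizes used in the checks

The property-based checks run at sizes chosen to exercise the combinatorics
while staying quick: 200 random schema multigraphs (up to 8 types, 20 typed
edges) against an exhaustive DFS path oracle; 100 random candidate sets for
the selection argmax; exhaustive LCS verification over all token pairs from
a two-letter alphabet up to length 4 plus randomized comparison against an
independent alignment-based LCS oracle; 500 random set triples for the
intersection algebra; and the 40-item seed-42 benchmark (10 per category)
for end-to-end recovery, where the expected exact-match rate and macro
ROUGE-L F1 are both 1.0 because gold text is produced by the same
verbalizer the pipeline uses.

## Known limitations

* The rule extractor understands the fixture templates and close variants,
  not free text; real deployments would use the LLM adapter and inherit
  its variance.
* Relation-seeking questions ($H_1 + T_1 \to R_?$) carry a known tail
  entity, a slot the frame supports as an extension; the executed pattern
  pins relation labels from the selected path, so the answer reports the
  labels of chains that actually connect the pair.
* Entities sharing one name are all used as anchors, but the first
  resolved type decides the path search.
* The Cypher subset is linear (no OPTIONAL MATCH, aggregation clauses or
  variable-length patterns); rendered queries remain valid input for live
  endpoints via the adapter seam.

## A worked example

```{r}
spec <- fixture_spec(seed = 42)
kg <- generate_kg(spec)
kg
bench <- generate_benchmark(kg, spec)
it <- bench[[31]]  # an attribute question
it$question
ans <- answer_question(kg, it$question)
attr(ans, "optimal_paths")
attr(ans, "cypher")
ans$text
identical(ans$answer_set$items, it$gold_answer_set)
```

```{r}
report <- run_benchmark(kg, bench)
report$macro
```
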