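#' Specification for a synthetic oncology knowledge graph
#'
#' The generator emulates the shape of a pan-cancer property graph: drugs,
#' genes, mutations, diseases and clinical trials, connected by
#' drug--treats--disease, drug--inhibits--gene, disease--has_mutation--mutation,
#' mutation--of_gene--gene, mutation--resistant_to--drug and
#' disease--has_trial--clinical_trial relations, with targeted-therapy flags
#' on drugs and recruitment age bounds on trials. Entity names are invented
#' (pronounceable drug/disease names, gene-symbol-like genes, protein-change
#' mutation labels, registry-style trial ids); the content is synthetic and
#' makes no biological claims.
#'
#' Defaults give every disease at least one mutation and at least one
#' clinical trial, and every drug at least one treated disease and one
#' inhibited gene, so all four question categories are instantiable.
#'
#' @param n_drugs,n_genes,n_mutations,n_diseases,n_trials Entity counts
#'   (all >= 1; `n_mutations >= n_diseases` and `n_trials >= n_diseases`
#'   guarantee coverage for multihop and attribute questions).
#' @param density Probability of each optional extra relation (additional
#'   treats/inhibits/has_mutation edges beyond the guaranteed ones).
#' @param max_age_range,min_age_range Inclusive integer ranges the trial
#'   recruitment-age attributes are drawn from (years).
#' @param questions_per_type Benchmark questions generated per reasoning
#'   category.
#' @param seed Integer seed fixing all randomness of the generator.
#' @return An object of class `kgqa_fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 15, n_genes = 12, n_mutations = 15,
                         n_diseases = 12, n_trials = 18, density = 0.12,
                         max_age_range = c(40, 90), min_age_range = c(18, 40),
                         questions_per_type = 10, seed = 42) {
  counts <- c(n_drugs, n_genes, n_mutations, n_diseases, n_trials)
  if (any(counts < 1)) stop_config_error("all entity counts must be >= 1")
  if (density < 0 || density > 1) stop_config_error("density must be in [0, 1]")
  structure(list(n_drugs = n_drugs, n_genes = n_genes,
                 n_mutations = n_mutations, n_diseases = n_diseases,
                 n_trials = n_trials, density = density,
                 max_age_range = max_age_range, min_age_range = min_age_range,
                 questions_per_type = questions_per_type,
                 seed = as.integer(seed)),
            class = "kgqa_fixture_spec")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.syllables <- c("ba", "ce", "da", "fe", "gi", "ko", "la", "mi", "ne", "po",
                "ra", "su", "ti", "vo", "xa", "zo", "lu", "qui")

unique_names <- function(n, make) {
  out <- character(0)
  while (length(out) < n) {
    cand <- make()
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}

gen_drug_names <- function(n) {
  suf <- c("nib", "mab", "olol", "stat", "parib", "ciclib")
  unique_names(n, function()
    paste0(paste(sample(.syllables, sample(2:3, 1), replace = TRUE), collapse = ""),
           sample(suf, 1)))
}

gen_gene_names <- function(n) {
  unique_names(n, function()
    paste0(paste(sample(LETTERS, 3, replace = TRUE), collapse = ""),
           sample(1:19, 1)))
}

gen_disease_names <- function(n) {
  hist <- c("carcinoma", "sarcoma", "lymphoma", "glioma", "melanoma", "adenoma")
  unique_names(n, function() {
    stem <- paste(sample(.syllables, 2, replace = TRUE), collapse = "")
    substr(stem, 1, 1) <- toupper(substr(stem, 1, 1))
    paste(stem, sample(hist, 1))
  })
}

# protein-change-style label derived from the mutation's own gene
gen_mutation_names <- function(genes_of) {
  out <- character(0)
  for (g in genes_of) {
    repeat {
      cand <- sprintf("%s p.%s%d%s", g, sample(LETTERS, 1), sample(1:999, 1),
                      sample(LETTERS, 1))
      if (!cand %in% out) break
    }
    out <- c(out, cand)
  }
  out
}

#' Generate a synthetic knowledge graph
#'
#' Deterministic under the spec's seed: two calls with the same spec produce
#' byte-identical node and edge tables. Every required schema edge is
#' present at least once; the guaranteed edges make every disease carry a
#' mutation and a trial (up to the available counts), and optional extra
#' edges are added with probability `density`.
#'
#' @param spec A [fixture_spec()].
#' @return A `kgqa_kg`.
#' @export
generate_kg <- function(spec) {
  stopifnot(inherits(spec, "kgqa_fixture_spec"))
  with_seed(spec$seed, {
    drug_names <- gen_drug_names(spec$n_drugs)
    gene_names <- gen_gene_names(spec$n_genes)
    disease_names <- gen_disease_names(spec$n_diseases)
    trial_names <- sprintf("NCT%07d", sample.int(9999999, spec$n_trials))

    # each mutation belongs to one gene; its label is derived from that gene
    mut_gene <- sample.int(spec$n_genes, spec$n_mutations, replace = TRUE)
    mutation_names <- gen_mutation_names(gene_names[mut_gene])

    ids <- list(drug = sprintf("d%03d", seq_len(spec$n_drugs)),
                gene = sprintf("g%03d", seq_len(spec$n_genes)),
                mutation = sprintf("m%03d", seq_len(spec$n_mutations)),
                disease = sprintf("s%03d", seq_len(spec$n_diseases)),
                clinical_trial = sprintf("t%03d", seq_len(spec$n_trials)))

    nodes <- data.frame(
      id = unlist(ids, use.names = FALSE),
      name = c(drug_names, gene_names, mutation_names, disease_names, trial_names),
      etype = rep(c("drug", "gene", "mutation", "disease", "clinical_trial"),
                  times = c(spec$n_drugs, spec$n_genes, spec$n_mutations,
                            spec$n_diseases, spec$n_trials)),
      targeted_therapy = "", oncogenic = "", maximum_age = "", minimum_age = "",
      stringsAsFactors = FALSE)
    is_drug <- nodes$etype == "drug"
    nodes$targeted_therapy[is_drug] <-
      ifelse(stats::runif(sum(is_drug)) < 0.5, "true", "false")
    is_mut <- nodes$etype == "mutation"
    nodes$oncogenic[is_mut] <- ifelse(stats::runif(sum(is_mut)) < 0.6, "true", "false")
    is_trial <- nodes$etype == "clinical_trial"
    nodes$maximum_age[is_trial] <-
      as.character(sample(spec$max_age_range[1]:spec$max_age_range[2],
                          sum(is_trial), replace = TRUE))
    nodes$minimum_age[is_trial] <-
      as.character(sample(spec$min_age_range[1]:spec$min_age_range[2],
                          sum(is_trial), replace = TRUE))

    edge <- function(h, l, t) data.frame(head_id = h, label = l, tail_id = t,
                                         stringsAsFactors = FALSE)
    edges <- list()

    # mutation--of_gene--gene (exactly one per mutation)
    edges[[length(edges) + 1]] <- edge(ids$mutation, "of_gene", ids$gene[mut_gene])

    # disease--has_mutation--mutation: first min(n_mut, n_dis) mutations cover
    # distinct diseases, the rest land on random diseases
    cover <- sample.int(spec$n_diseases)
    mut_dis <- integer(spec$n_mutations)
    k <- min(spec$n_mutations, spec$n_diseases)
    mut_dis[seq_len(k)] <- cover[seq_len(k)]
    if (spec$n_mutations > k)
      mut_dis[(k + 1):spec$n_mutations] <-
        sample.int(spec$n_diseases, spec$n_mutations - k, replace = TRUE)
    edges[[length(edges) + 1]] <- edge(ids$disease[mut_dis], "has_mutation", ids$mutation)

    # drug--treats--disease and drug--inhibits--gene (>= 1 each per drug)
    for (i in seq_len(spec$n_drugs)) {
      dis <- sample.int(spec$n_diseases, 1)
      extra <- which(stats::runif(spec$n_diseases) < spec$density)
      for (s in unique(c(dis, extra)))
        edges[[length(edges) + 1]] <- edge(ids$drug[i], "treats", ids$disease[s])
      gn <- sample.int(spec$n_genes, 1)
      extra_g <- which(stats::runif(spec$n_genes) < spec$density)
      for (g in unique(c(gn, extra_g)))
        edges[[length(edges) + 1]] <- edge(ids$drug[i], "inhibits", ids$gene[g])
    }

    # mutation--resistant_to--drug (at least one overall)
    res <- which(stats::runif(spec$n_mutations) < 0.4)
    if (length(res) == 0) res <- 1L
    edges[[length(edges) + 1]] <-
      edge(ids$mutation[res], "resistant_to",
           ids$drug[sample.int(spec$n_drugs, length(res), replace = TRUE)])

    # disease--has_trial--clinical_trial: first min(n_trials, n_dis) trials
    # cover distinct diseases
    cover_t <- sample.int(spec$n_diseases)
    tri_dis <- integer(spec$n_trials)
    kt <- min(spec$n_trials, spec$n_diseases)
    tri_dis[seq_len(kt)] <- cover_t[seq_len(kt)]
    if (spec$n_trials > kt)
      tri_dis[(kt + 1):spec$n_trials] <-
        sample.int(spec$n_diseases, spec$n_trials - kt, replace = TRUE)
    edges[[length(edges) + 1]] <- edge(ids$disease[tri_dis], "has_trial", ids$clinical_trial)

    edges <- unique(do.call(rbind, edges))
    rownames(edges) <- NULL
    load_kg(nodes, edges)
  })
}

## --- traversal oracle ---------------------------------------------------
# Gold answers are computed straight off the edge table, independently of
# the schema-inference and query modules, so pipeline-vs-gold agreement is a
# genuine end-to-end check.

oracle_neighbors <- function(kg, id, label, other_type) {
  e <- kg$edges
  rows <- which((e$head_id == id | e$tail_id == id) & e$label == label)
  out <- data.frame(other = character(0), row = integer(0), stringsAsFactors = FALSE)
  for (r in rows) {
    other <- if (e$head_id[r] == id) e$tail_id[r] else e$head_id[r]
    if (entity_type(kg, other) == other_type)
      out <- rbind(out, data.frame(other = other, row = r, stringsAsFactors = FALSE))
  }
  out
}

#' Traversal oracle for benchmark gold answers
#'
#' Follows the stated relation labels directly on the edge table (no schema
#' reasoning, no query generation) and returns the gold answer set together
#' with the supporting chains. Used by [generate_benchmark()] and as the
#' independent reference in end-to-end tests.
#'
#' @param kg A `kgqa_kg`.
#' @param head_id Anchor entity id.
#' @param labels Character vector of relation labels to follow.
#' @param types Character vector of target entity types, parallel to `labels`.
#' @return List with `ids` (terminal entity ids) and `chains`
#'   (canonically sorted `kgqa_chain` objects).
#' @export
oracle_traverse <- function(kg, head_id, labels, types) {
  partial <- list(list(ids = head_id, rows = integer(0)))
  for (i in seq_along(labels)) {
    nxt <- list()
    for (p in partial) {
      last <- p$ids[length(p$ids)]
      nb <- oracle_neighbors(kg, last, labels[i], types[i])
      for (j in seq_len(nrow(nb))) {
        if (nb$other[j] %in% p$ids) next
        nxt[[length(nxt) + 1]] <- list(ids = c(p$ids, nb$other[j]),
                                       rows = c(p$rows, nb$row[j]))
      }
    }
    partial <- nxt
  }
  chains <- sort_chains(lapply(partial, function(p) make_chain(kg, p$ids, p$rows)))
  list(ids = unique(vapply(chains, chain_terminal_id, character(1))),
       chains = chains)
}

# Build gold text exactly the way the pipeline composes answers: sorted
# items plus per-chain evidence sentences.
gold_text <- function(kg, items, chains, return_spec = "terminal-entities",
                      attr_keys = character(0)) {
  sg <- make_subgraph(kg, chains)
  sentences <- vapply(sg$chains, sentence_for_chain, character(1),
                      subgraph = sg, return_spec = return_spec,
                      attr_keys = attr_keys)
  compose_answer(sentences, answer_set(sort_c(unique(items)),
                                       return_spec = return_spec))$text
}

#' Generate a four-category question benchmark from a synthetic graph
#'
#' Instantiates template questions for the four reasoning categories --
#' one-hop (tail entities one relation away from the head), multihop (tail
#' entities reached through an intermediate entity), intersection (two heads
#' whose tail sets must overlap, enforced by construction), and attribute
#' (arg-max over a terminal attribute) -- sampling anchor entities so that
#' every gold answer set is non-empty. Gold answers come from the traversal
#' oracle ([oracle_traverse()]), never from the question-answering pipeline,
#' and the gold relational path is recorded per item.
#'
#' @param kg The graph from [generate_kg()] (same spec).
#' @param spec The [fixture_spec()] used to generate `kg`.
#' @return List of benchmark items, each with fields `id`, `question`,
#'   `reasoning_type`, `heads`, `gold_path`, `gold_answer_set`,
#'   `gold_answer_text`.
#' @export
generate_benchmark <- function(kg, spec) {
  stopifnot(inherits(kg, "kgqa_kg"), inherits(spec, "kgqa_fixture_spec"))
  n <- spec$questions_per_type
  e <- kg$edges
  nm <- function(id) entity_name(kg, id)

  with_seed(spec$seed + 1L, {
    items <- list()
    add <- function(it) items[[length(items) + 1]] <<- it

    pick <- function(pool, n, what) {
      pool <- sort_c(unique(pool))
      if (length(pool) < n)
        stop_config_error(sprintf(
          "graph too sparse for %d %s questions (only %d eligible anchors)",
          n, what, length(pool)))
      sample(pool, n)
    }

    # one-hop: drug --treats--> diseases
    for (d in pick(e$head_id[e$label == "treats"], n, "one-hop")) {
      tr <- oracle_traverse(kg, d, "treats", "disease")
      add(list(
        question = sprintf("What types of cancer can be treated with %s?", nm(d)),
        reasoning_type = "one-hop", heads = nm(d),
        gold_path = verbalize_path(rel_path(c("drug", "disease"), "treats")),
        gold_answer_set = unname(sort_c(vapply(tr$ids, nm, character(1)))),
        gold_answer_text = gold_text(kg, unname(vapply(tr$ids, nm, character(1))), tr$chains)))
    }

    # multihop: disease --has_mutation--> mutation --of_gene--> gene
    for (s in pick(e$head_id[e$label == "has_mutation"], n, "multihop")) {
      tr <- oracle_traverse(kg, s, c("has_mutation", "of_gene"),
                            c("mutation", "gene"))
      add(list(
        question = sprintf("Which gene has a mutation present in %s?", nm(s)),
        reasoning_type = "multihop", heads = nm(s),
        gold_path = verbalize_path(rel_path(c("disease", "mutation", "gene"),
                                            c("has_mutation", "of_gene"))),
        gold_answer_set = unname(sort_c(vapply(tr$ids, nm, character(1)))),
        gold_answer_text = gold_text(kg, unname(vapply(tr$ids, nm, character(1))), tr$chains)))
    }

    # intersection: drugs that treat a disease AND inhibit a gene; pairs are
    # enumerated so the intersection is non-empty by construction
    pairs <- unique(do.call(rbind, lapply(
      unique(e$head_id[e$label == "treats"]), function(d) {
        dis <- e$tail_id[e$label == "treats" & e$head_id == d]
        gen <- e$tail_id[e$label == "inhibits" & e$head_id == d]
        if (length(dis) == 0 || length(gen) == 0) return(NULL)
        expand.grid(disease = dis, gene = gen, stringsAsFactors = FALSE)
      })))
    if (is.null(pairs) || nrow(pairs) < n)
      stop_config_error(sprintf(
        "graph too sparse for %d intersection questions", n))
    key <- paste(pairs$disease, pairs$gene)
    pairs <- pairs[order(key, method = "radix"), , drop = FALSE]
    sel <- sample.int(nrow(pairs), n)
    for (i in sel) {
      s <- pairs$disease[i]; g <- pairs$gene[i]
      tr1 <- oracle_traverse(kg, s, "treats", "drug")
      tr2 <- oracle_traverse(kg, g, "inhibits", "drug")
      common <- intersect(tr1$ids, tr2$ids)
      ch1 <- tr1$chains[vapply(tr1$chains, chain_terminal_id, character(1)) %in% common]
      ch2 <- tr2$chains[vapply(tr2$chains, chain_terminal_id, character(1)) %in% common]
      add(list(
        question = sprintf("Which drugs can treat %s and inhibit %s?", nm(s), nm(g)),
        reasoning_type = "intersection", heads = c(nm(s), nm(g)),
        gold_path = paste(
          verbalize_path(rel_path(c("disease", "drug"), "treats")),
          verbalize_path(rel_path(c("gene", "drug"), "inhibits")), sep = " | "),
        gold_answer_set = unname(sort_c(vapply(common, nm, character(1)))),
        gold_answer_text = gold_text(kg, unname(vapply(common, nm, character(1))),
                                     c(ch1, ch2))))
    }

    # attribute: maximum recruitment age over a disease's trials
    for (s in pick(e$head_id[e$label == "has_trial"], n, "attribute")) {
      tr <- oracle_traverse(kg, s, "has_trial", "clinical_trial")
      ages <- vapply(tr$ids, function(id) {
        v <- entity_attrs(kg, id)$maximum_age
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
      best <- max(ages, na.rm = TRUE)
      winners <- tr$ids[!is.na(ages) & ages == best]
      chains <- tr$chains[vapply(tr$chains, chain_terminal_id, character(1)) %in% winners]
      add(list(
        question = sprintf(
          "What is the maximum age for recruitment of clinical trials for patients with %s?",
          nm(s)),
        reasoning_type = "attribute", heads = nm(s),
        gold_path = verbalize_path(rel_path(c("disease", "clinical_trial"), "has_trial")),
        gold_answer_set = format_attr_value(best),
        gold_answer_text = gold_text(kg, format_attr_value(best), chains,
                                     return_spec = "terminal-attributes",
                                     attr_keys = "maximum_age")))
    }

    for (i in seq_along(items)) items[[i]] <- c(list(id = sprintf("q%03d", i)),
                                                items[[i]])
    items
  })
}

#' Write / read a benchmark as JSON
#'
#' @param items Benchmark items from [generate_benchmark()].
#' @param path Output (or input) path.
#' @return `write_benchmark`: invisibly, the path. `read_benchmark`: the
#'   item list.
#' @export
write_benchmark <- function(items, path) {
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  items <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(items, function(it) {
    it$heads <- as.character(unlist(it$heads))
    it$gold_answer_set <- as.character(unlist(it$gold_answer_set))
    it$gold_answer_text <- as.character(unlist(it$gold_answer_text))
    it
  })
}

#' Write fixture files (graph CSVs and benchmark JSON)
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kg <- generate_kg(spec)
  nodes_csv <- file.path(dir, "nodes.csv")
  edges_csv <- file.path(dir, "edges.csv")
  bench_json <- file.path(dir, "benchmark.json")
  write_kg(kg, nodes_csv, edges_csv)
  write_benchmark(generate_benchmark(kg, spec), bench_json)
  invisible(c(nodes = nodes_csv, edges = edges_csv, benchmark = bench_json))
}
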