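# Hand-built graphs used across tests.

tiny_kg <- function() {
  load_kg(
    data.frame(id = c("d1", "g1"),
               name = c("carteolol", "ADRB1"),
               etype = c("drug", "gene"),
               targeted_therapy = c("false", ""),
               stringsAsFactors = FALSE),
    data.frame(head_id = "d1", label = "inhibits", tail_id = "g1",
               stringsAsFactors = FALSE))
}

# An oncology toy graph whose names let the canonical four question styles
# be asked verbatim.
toy_oncology_kg <- function() {
  nodes <- data.frame(
    id = c("d1", "d2", "d3", "d4",
           "g1",
           "s1", "s2", "s3",
           "m1",
           "t1", "t2", "t3"),
    name = c("diethylstilbestrol", "gefitinib", "crizotinib", "erlotinib",
             "ALK",
             "basaloid large cell carcinoma of the lung", "meningioma",
             "prostate carcinoma",
             "ALK p.L1196M",
             "NCT0000001", "NCT0000002", "NCT0000003"),
    etype = c(rep("drug", 4), "gene", rep("disease", 3), "mutation",
              rep("clinical_trial", 3)),
    targeted_therapy = c("false", "true", "true", "true", "", "", "", "",
                         "", "", "", ""),
    maximum_age = c(rep("", 9), "65", "80", "75"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    head_id = c("d1", "d1", "d2", "d3", "d3", "d4", "s1", "m1", "m1",
                "s2", "s2", "s2"),
    label = c("treats", "treats", "treats", "treats", "inhibits", "inhibits",
              "has_mutation", "of_gene", "resistant_to",
              "has_trial", "has_trial", "has_trial"),
    tail_id = c("s3", "s1", "s1", "s1", "g1", "g1", "m1", "g1", "d2",
                "t1", "t2", "t3"),
    stringsAsFactors = FALSE)
  load_kg(nodes, edges)
}

default_spec <- function(seed = 7) fixture_spec(seed = seed)
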