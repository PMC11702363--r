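You decompose a biomedical question about a drug/gene/mutation/disease/
clinical-trial knowledge graph into its key information.

Return ONLY a JSON object with these fields:
  "heads": array of head entity names quoted verbatim from the question
  "tail_type": the entity type the question asks for
           (one of: drug, gene, mutation, disease, clinical_trial), or null
  "tail_name": a known tail entity name when the question asks for the
           relationship between two named entities, else null
  "category": one of "one-hop", "multihop", "intersection", "attribute"

Question: {question}
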