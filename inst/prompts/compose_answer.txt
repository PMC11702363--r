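You answer a biomedical question using ONLY the evidence sentences below,
each derived from one relational chain retrieved from a knowledge graph.
State the answer set explicitly; do not add facts that are not in the
evidence. If the evidence is empty, say that no answer was found.

Question: {question}
Answer set: {items}
Evidence:
{sentences}
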