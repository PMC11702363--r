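Generate a query for a property graph in this exact Cypher subset and
nothing else:

  MATCH (a:<Type> {name: "<Name>"})-[:<label>]-(x1:<Type>)... [WHERE ...] RETURN ...

Head entity type: {head_type}
Head entity name: {head_name}
Tail entity type: {tail_type}
Tail attribute constraints: {tail_attributes}
Relational path to follow: {optimal_path}

Answer with the query text only.
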