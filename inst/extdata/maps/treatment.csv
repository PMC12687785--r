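original_value,curated_ontology_term,curated_ontology_term_id,curated_ontology_term_db
metformin,Metformin,NCIT:C61612,NCIT
sitagliptin,Sitagliptin,NCIT:C73838,NCIT
lantus,Insulin Glargine,NCIT:C29125,NCIT
solostar,Insulin Glargine,NCIT:C29125,NCIT
novorapid,Insulin Aspart,NCIT:C48026,NCIT
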