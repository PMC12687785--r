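format-version: 1.2
! Synthetic offline snapshot: a hand-trimmed subset of the human ancestry
! ontology around the 'ancestry category' node, for demonstrations and tests.
! Not a redistribution of the full ontology; local snapshot ids/labels only.

[Term]
id: HANCESTRO:0004
name: ancestry category

[Term]
id: HANCESTRO:0005
name: European
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0008
name: Asian
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0010
name: African
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0013
name: American
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0014
name: Hispanic or Latin American
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0015
name: Greater Middle Eastern (Middle Eastern or North African or Persian)
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0017
name: Oceanian
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0018
name: Other admixed ancestry
is_a: HANCESTRO:0004 ! ancestry category

[Term]
id: HANCESTRO:0021
name: East Asian
synonym: "East Asian ancestry" EXACT []
is_a: HANCESTRO:0008 ! Asian

[Term]
id: HANCESTRO:0023
name: South Asian
is_a: HANCESTRO:0008 ! Asian

[Term]
id: HANCESTRO:0019
name: Northern European
is_a: HANCESTRO:0005 ! European

[Term]
id: HANCESTRO:0020
name: Southern European
is_a: HANCESTRO:0005 ! European
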