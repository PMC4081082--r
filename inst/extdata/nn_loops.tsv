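parameter	value
hairpin_a	5.6
hairpin_b	1.08
bulge_a	3.8
bulge_b	1.08
internal_a	1.7
internal_b	1.08
ml_close	3.4
ml_branch	0.4
ml_unpaired	0
min_hairpin	3
max_interior	30
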