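group_label,assay,category_a,category_b
tetraploid_a,seed_set,171,507
tetraploid_a,progeny,327,25
simplex_b,seed_set,16,250
simplex_b,progeny,321,86
triplex_b,seed_set,309,232
triplex_b,progeny,208,0
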