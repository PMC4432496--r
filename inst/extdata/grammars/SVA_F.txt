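# Youngest human subfamily: 5' array ABCAAAB'CACAAF, internal K_nGC'
# arrays, 3' array KGC'T.
name: SVA_F
prefix: A B C A A A B' C A C A A F
interior: motif
interior_tokens: K G C'
interior_variable_pos: 1
interior_copy_range: 1 4
interior_reps: 4 6
interior_first_token: K'
suffix: K G C' T
mutation_rate: 0.01
indel_rate: 0.1
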