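# Younger subfamily: internal K_nGC' arrays, KGC'T 3' array; the 5'-most
# K of the arrays is the K' variant. Prefix beyond ABCA is synthetic.
name: SVA_D
prefix: A B C A A A B' C A
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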