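# Chimpanzee-specific SVA_D-derived subfamily; same internal and 3'
# arrays as SVA_D. Prefix beyond ABCA is synthetic.
name: SVA_PtA
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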