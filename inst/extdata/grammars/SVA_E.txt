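# SVA_E adds LL'GC'/C'' arrays to the interior; synthetic emulation.
name: SVA_E
prefix: A B C A A A B' C A C A
interior: motif
interior_tokens: L L' G C''
interior_variable_pos: 1
interior_copy_range: 1 2
interior_reps: 3 4
suffix: K G C' T
mutation_rate: 0.01
indel_rate: 0.1
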