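# Younger orangutan subfamily: central arrays amplify C-type units
# scaffolded by Q-type units; 3' array differs from the internal array.
# Synthetic emulation.
name: SVA_PA_8
prefix: A B5' C A Q
interior: motif
interior_tokens: Q C
interior_variable_pos: 2
interior_copy_range: 2 4
interior_reps: 4 6
suffix: R C' T
mutation_rate: 0.01
indel_rate: 0.1
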