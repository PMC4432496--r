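# D-type unit and the C^T sub-terminal variant emerge with B1A;
# synthetic emulation.
name: LAVA_B1
prefix: A B B D
interior: random
interior_tokens: B C D
interior_len_range: 3 8
suffix: CT B
mutation_rate: 0.01
indel_rate: 0.1
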