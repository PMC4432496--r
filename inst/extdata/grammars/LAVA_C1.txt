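# N-type 53 bp unit at the second 5' position from C1 onwards;
# synthetic emulation.
name: LAVA_C1
prefix: A N B B
interior: random
interior_tokens: B C D
interior_len_range: 3 8
suffix: CT B
mutation_rate: 0.01
indel_rate: 0.1
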