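# Oldest LAVA subfamily: short 5'/3' conserved arrays only; synthetic
# emulation.
name: LAVA_A
prefix: A B B
interior: random
interior_tokens: A B C
interior_len_range: 3 8
suffix: C B
mutation_rate: 0.01
indel_rate: 0.1
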