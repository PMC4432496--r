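# ANBB 5' array; O/P units join the terminal array with the C^TT
# sub-terminal variant; synthetic emulation.
name: LAVA_E
prefix: A N B B D
interior: random
interior_tokens: B C D
interior_len_range: 4 9
suffix: O P CTT B
mutation_rate: 0.01
indel_rate: 0.1
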