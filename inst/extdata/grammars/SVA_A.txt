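# Oldest human SVA subfamily: short conserved 5' array, no organized
# interior (D-type units occasionally intrude); synthetic emulation.
name: SVA_A
prefix: A B C A
interior: random
interior_tokens: B C D
interior_len_range: 3 8
suffix: T
mutation_rate: 0.01
indel_rate: 0.1
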