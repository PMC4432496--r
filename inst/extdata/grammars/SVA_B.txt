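# First subfamily carrying the longer E/G/H/I units; unstructured
# interior; C-type sub-terminal unit; synthetic emulation.
name: SVA_B
prefix: A B C A A B'
interior: random
interior_tokens: E G H I C
interior_len_range: 4 10
suffix: C T
mutation_rate: 0.01
indel_rate: 0.1
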