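# I-type units amplify in the interior; synthetic emulation.
name: SVA_C
prefix: A B C A A B' C
interior: random
interior_tokens: I G C'
interior_len_range: 4 10
suffix: C T
mutation_rate: 0.01
indel_rate: 0.1
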