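# Youngest LAVA subfamily; lacks the N-type second unit; synthetic
# emulation.
name: LAVA_F
prefix: A B B D
interior: random
interior_tokens: B C D
interior_len_range: 4 9
suffix: O P CTT B
mutation_rate: 0.01
indel_rate: 0.1
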