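>A||shared|PARENTS=|NOTE=ancestral 40 bp RU
GCCCTCCGGGGTGGGAGTCTTGTTTCCTGATGCGGGGGGC
>B||shared|PARENTS=|NOTE=ancestral 39 bp RU
GCTGAGACACGAGACGAGCATGAGGCACGCTGGCCGATC
>C||shared|PARENTS=A|NOTE=short 37 bp RU; A minus 3 bp
GCCCTCCGGGGTGGGAGTCTTTCCTGATGCGGGGGGC
>D||LAVA|PARENTS=A|NOTE=second 40 bp RU of LAVA
GCCCTCCGGGGTGGCAGTCTTGTTTCCCGATGTGGGAGGC
>E||SVA|PARENTS=B|NOTE=41 bp; appears with SVA_B
GCTGAGACACGAGACGCGAGCATGAGGCACGCTGGCCGATC
>F||SVA|PARENTS=E|NOTE=41 bp; closes the SVA_F 5' array
CCTGCGACACGCGACGCGAACATGAGGCACGCTGGCTGATC
>G||SVA|PARENTS=E|NOTE=41 bp; member of the KGC' arrays
GCTGAGACACGAGGCGCGGGCACGAGGCACGCTGGCCGATC
>H||SVA|PARENTS=E|NOTE=42 bp intermediate; lost after SVA_C
GCTGAGACACGAGACGCGAGCATGAGGCACGGCTGGCCGATC
>I||SVA|PARENTS=H|NOTE=47 bp intermediate amplified in SVA_B/SVA_C
GCTGAGACACGTGGCAGGACGCGAGCCTGAGGCACGGCTGGCCGATC
>J||SVA|PARENTS=A|NOTE=figure-only
GCCCTCCAGGGTGGGAGTCTCGTTGCCTGATGCGGGGGGC
>K||SVA|PARENTS=I|NOTE=49 bp G-rich RU of the internal K_nGC' arrays
GCTGAGACAAGTGGCAGGACGCGAGCCTGAGGCACGGCGGGGGCCGATC
>L||SVA|PARENTS=K|NOTE=48 bp; SVA_E LL'GC' arrays
GCTGAGACAAGTGGCAGGACGGGACCTAAGGCACGGCGGGGGCCAATC
>M||SVA|PARENTS=B|NOTE=figure-only
GGTGAGACACGAGACGATCATGAGGCACACTGGCCGATC
>N||LAVA|PARENTS=D|NOTE=53 bp; second 5' RU from LAVA_C1 onwards
GCCCTCCGGGGTGGCAGTGCCAGGCGTGGCCCTTGTTTCCCGATGTGGGAGGC
>O||LAVA|PARENTS=C|NOTE=42 bp; LAVA_E terminal array
GCCCTCCGGGGGCTCGTGGGAGTCTTTCCTGATGCGGGGGGC
>P||LAVA|PARENTS=O|NOTE=42 bp; LAVA_E terminal array
GCCCTCCGGGGGTTCGTGGGCGTCTGTTCTGATGCGGGGGGC
>Q||orangutan_SVA|PARENTS=C|NOTE=43 bp scaffold RU of orangutan central arrays
GCCCTCCGGGGTGGGAGTCTTTCCTCAGGGCGATGCGGGGGGC
>R||orangutan_SVA|PARENTS=B|NOTE=38 bp; orangutan SVA_PA_7-11
GCTGAGACAGAGACGAGCATGAGGCACGCTGGCCGATC
>S||chimp_SVA|PARENTS=|NOTE=derivation_undetermined
GCATGCCCAGGGTGCTCGCGGCGGCGGCAAGGCCCGAGAGT
>T||SVA|PARENTS=B|NOTE=terminal=true; 3' terminal RU
GCTGAGACACGAGACGAGTTTGAGGCACGC
>A|5'|shared|PARENTS=|NOTE=LAVA 5'-most A-type RU
GCCCTCCGGGCTGGGAGTCTTGTTGCCTGATGCGGGGGGC
>B|'|shared|PARENTS=|NOTE=second B-type RU of SVA_B-F 5' arrays
GCTGAGACACGAGACGAGCATGATGCACGCTGGCCTATC
>B|5'|shared|PARENTS=|NOTE=5'-most B-type RU; orangutan SVA and LAVA_B2
GCTGAGACACGAAAAGAGCATGAGGCACGCTGGCCAATC
>B|CCA|shared|PARENTS=|NOTE=LAVA_B2C internal B-type RU
GCTGAGACACCAGACGAGCATGAGGCACGCTGGCCGATC
>C|'|shared|PARENTS=|NOTE=short C-type of the SVA KGC' arrays
GCCCTCCGGGGTGGGAGTCTTCCCTGATGCGGGGGGC
>C|''|shared|PARENTS=|NOTE=SVA_E LL'GC'/C'' arrays
GCCCTCCAGGGTGGAAGTCTTTCCTGATGCGGGGGGC
>C|T|shared|PARENTS=|NOTE=LAVA sub-terminal C variant from B1A
GCCCTCCGGGGTGGGAGTCTTTCCTGATACGGGGGGC
>C|TT|shared|PARENTS=|NOTE=LAVA sub-terminal C variant, C4/D/E
GCCCTCCGGGGTTGGAGTCTTTCCTGATGCGGGGGGG
>C|5'|shared|PARENTS=|NOTE=LAVA_B2B 5' C-type RU
GACCTCCGGGGTGGGAATCTTTCCTGATGCGGGGGGC
>C|C2|shared|PARENTS=|NOTE=LAVA_C2 specific
GCCCTCCGGGGTGGGAGTCTTTCCTGATGATGGGGGC
>D|C2|LAVA|PARENTS=|NOTE=LAVA_C2 specific
GCCCCCCGGGGTGGCAGCCTTGTTTCCCGATGTGGGAGGC
>K|'|SVA|PARENTS=|NOTE=5' end of SVA internal K arrays
GTTGAGACAAGTGGCAGGACGCGAGCCTGAGGCACGGCGGGGCCCGATC
>L|'|SVA|PARENTS=|NOTE=SVA_E LL' arrays
GCTGAGACAGGTGGCAGGACGGGACCTAAGGCACGGCGGGGGCCGATC
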