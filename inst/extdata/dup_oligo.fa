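>dup_oligo chr5:1295182 TERT promoter c.-100_-79 duplication EMSA oligo (82 nt variant sequence)
AGGGCGGGGCCGCGGAAAGGAAGGGGCGGGGCCGCGGAAAGGAAGGGGAGGGGCTGGGAG
GGCCCGGAGGGGGCTGGGCCGG
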