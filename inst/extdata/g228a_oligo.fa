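>g228a_oligo chr5:1295182 TERT core promoter G228A mutant EMSA oligo (60 nt)
AGGGCGGGGCCGCGGAAAGGAAGGGGAGGGGCTGGGAGGGCCCGGAAGGGGCTGGGCCGG
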