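>wt_oligo chr5:1295182 TERT core promoter wild-type EMSA oligo (60 nt)
AGGGCGGGGCCGCGGAAAGGAAGGGGAGGGGCTGGGAGGGCCCGGAGGGGGCTGGGCCGG
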