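>promoter_window_reconstructed chr5:1295171 TERT core promoter window, GGAA-bearing strand, reconstructed from the published promoter sequence; byte-identical to the printed wild-type EMSA oligo over chr5:1295182-1295241
GCCGCGAGGAGAGGGCGGGGCCGCGGAAAGGAAGGGGAGGGGCTGGGAGGGCCCGGAGGG
GGCTGGGCCGGGGACCCGGGAGGGGTCGGGACGGGGCGGGGTCCGCGCGGAGGAGGCGGA
GCTGGAAGGT
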