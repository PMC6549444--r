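>TpiI4Ca1b_ins synthetic 200-bp insertion
CGCGGGGTACAGACTCGTACCTGACGTCCAGTGAATCGGAAATATGAACGCGATGCGCCTTGGTGCATGCACCTAGCCGACCTCTGACTGTATGTGCGACCAACGACTCCACGCCATCCTAGGACTGCACGCTGGAATTGGCAGCCCCGAATTGCTGGTGGCCTTTCGTAAAGGATTGGTATTTTTTGTGTCGCTAGTCG
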