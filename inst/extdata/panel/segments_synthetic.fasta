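>COIB synthetic segment reference (corn-strain consensus, h4)
CAGCGAGAGACTAGAATGAAATGTAGCGCGGTTTGTTGTCGTGAGAAGCTAAGGATAATTACGGATGTGTTAATAGGGATGGGCATTTCAAATGAGGGTCAGGGTTGCGTGCCACTGTTCTGGGTGTGCGTGTTTCCAGGACGTGAGCACCTGAGCCCCGAGGACAAAAAGTTCCCGTTGGCGAGGGATTTAGCATTTTATGCGTTCAGGAGGTAACCCTTTGGGTAGTGCTTACCCTCTCGTCTTTAATCTCCTCCTTTTATCCCGGAAGGTCCAATCGCGTGTGTGACTAGGGCCGAGTAGCTCCGATGACTTCTATGTCAGCAGAGGACCTAGACTCCGTTGGAGAAGATCTAAAATTTGACGACCGTAAAACGGTAACATCCCCGCTGATAGATACCCTGGTTGTGTAACTGCGCTGCGTCTTCTGTGCGAGGCGTATTGCGCTGCGTCCAGCTAACAGCGGAGTTGGCGGAATTGAACGAAGTGCAAAGTTATACTTCTCAGAATGTTGGTCTCGGCACCCATCATTCAAAACAGTGCGTTGGGATAAGATGAACTCTTCCCGCACTGAAAAAGTCGTCCGGGATTGCAACAGTGTTT
>TpiE4 synthetic segment reference (TpiCa1 state)
CCCGGCCCTCAATTGTTGCGGCACGGGGTGCTTCCAACAGTCTCTCAGGATGCAGCTTACCTAACCTATGACCCCACCTCTAGCCGTTATCGTTTCGGGTCGCTGTAGCCAGCAGGTCTTTTGTAGTATCGGGCGGACGACCAAAAAAGCCGGTGCCACGTATCCCACCGGCTCTAGGTTGCCACAAAGGGCATTGGCC
>TpiI4 synthetic segment reference (TpiI4Ca1a core, intron 10-172)
CAGACCAGCATACTTTAGCCAATCTAAACAAGACCGTACGAGGATGAGTGGTTGATCGTGCCAGGCCAGTATCCCTGCTCGGCATAGTCGTGCCGGCTATGGTGCCAGCCTAGTGGGCTTTGCTCTACGGCTTTACTGAATTTCACTGTATTGTGGTACGGTT
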