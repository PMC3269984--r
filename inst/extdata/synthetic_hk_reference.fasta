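>synth_snoRNA_01
GCAAAATCAGGAATTGAGCGCAAGTAATCTTCAAGTACAGTGGGTTGACTACGCCTAAGG
AGAGCTTTTGTTTAATGGCCGGTAGCACCCACTATATTTCATTAGAACTA
>synth_snoRNA_02
GTTACTAATTGGGGCTTCCGGAGAAATCTCTTTTCTCATCAGAGCGCTTTGGATTTAGAT
CTCGCTCTGTGTACTTTACTGCAAGTCTAATATCT
>synth_snoRNA_03
TTGGCGTTGAGAAGAGTTCACACTGTATTTCAAATGTTGAACTATTTATCGGGAAGAGTG
CATCTATAATAGGATGGCAGGTACGCCCATACAGCCCATTGCCTATGAATTTATCGAAGT
TTTTCTACCC
>synth_snoRNA_04
TCTTAATCTCACGCGATAACAGGATCGTTTAGAAACTTAAGATATTGCTCAAGTAAATCT
AACGCTACCAGTCCCACAGTGAATAATACAGCTGGCGAACCTATCGGTTGAACCGCCATG
>synth_tRNA_01
AATCCTAATTAGACAAAAAACATATGCAGAAGCGAAAAAACTGGACGAGGGTTTACCTTC
TGACTTAAAAGCAACCTAATGG
>synth_tRNA_02
AGCGTACATTATACACTCATCGGGATTATTCGCCACCTATCAAAACTGCCCTACACTCTC
ATGTACGAATCGGCAAAGCTTTCGCGGG
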