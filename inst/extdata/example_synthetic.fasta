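>Aquifex
ATCTAGACCCCAGATAACTCGCCGCGGTATGTTTTTCGGCGTCTGTTACGGGAGCCCTACGGCGCTAGGCGGCGAGCGAATCGTAGCGAACCGTCACCACGTGGATGTTTCTCCGAAAGG
>Bacillus
ATCTAGACCCCATATAACTCGCCGCGGTATGTTTTCCGGCGTCTGTTACGGGAGCCCTACGGCGCTAGGCGGCGAGCGAATCGTAGCGAACCGTCACCACGTGGATGTTTCTCCGAAAGG
>Deinococcus
GTCTAGACCCCAGGTAATTCCCAGCGGTATGTTCTTCGGCGTCTGCTACGGGAGCCCTAACGCTCTAGGCTGCGAGCGAATCGTAGCGAACCGTGGACACGTGGATGTCCCATCGACAGG
>Thermus
ATCTAGACCCCAGGTAATTCCCAGCGGCATGTTCTTCGGCGTCTGCTACGGGAGCTCTAACGCTCTAGGCTGCGAGCGAATCGTAGCGAACCGTCAACACGTGGATGTCCCATCGACAGG
>Thermotoga
ATATAGACCGCATGGAATTCGCCGCAGTATGGTTGTCGGCGTCTGTAGCGGCAGCCCTACGGCGCTGGGCTGCGGACGGATCGTAGCGAAGCGTCAGCACGAGGAGGTTTCTTCCAAAGG
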