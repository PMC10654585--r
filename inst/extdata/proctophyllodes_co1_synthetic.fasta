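>Proctophyllodes_molothrus_1
CCTGGCAATCTGCACACTCCGTATTTATGCGCAGCTAAACGCGCTTTTGTTAATGAGTTGCGGATGTAGC
ATGCTATTTATTAGCTTGAGTGCTCCTCTCATAGCGTCTATGACCTGCCCTGCCGCAGGATATGTGCCAA
GCATATGATAGCTGGGAGTGTCATTAAAAATGTCTTAGAGGGGAGAGGTGGTCGCACGGAGAAATGAACA
AGATGGTGGCGTGACTGTTCTCTCTTGCCGAACGTTTATGAAGATGGCATTTACGCCCGCGCAGAATCGT
AGAAGTACAGCAACGTCAGGAAGAATCCCTAAGCGCGTAGTTGGCCGTCGCACGATGCACCAATGATCTG
AATCTCTAGTTTTCAGTCCTACGACTACAATCCGCAATAGAATGGCGAACAGGCGGCGCCATAAGTTGAT
TGGTATTGGTTAACAAAATAGGTGTCTGGACGGGTTTATTGCATTCAGCCGCAAGAAACAAATTACTGTT
AACCACGTCTCGTTACATCGACGGGCTCTCGGAATCCGGACCAAGGCAATCTAGACACATTTGGCTTGGG
GTCTCTCTGGGCTTGGATTCCAAGCCCTATCACTAGTTTC
>Proctophyllodes_molothrus_2
CCTGGCAATCTGCACACTCCGTATTTATGCGCAGCTAAACGCGCTTTTGTTAATGAGTTGCGGATGTAGC
ATGCTATTTATTAGCTTGAGTGCTCCTCTCATAGCGTCTATGACCTGTCCTGCCGCAGGATATGTGCCAA
GCATATGATAGCTGGGAGTGTCATTAAAAATGTCTTAGAGGGGAGAGGTGGTCGCACGGAGAAATGAACA
AGATGGTGGCGTGACTGTTCTCTCTTGCCGAACGTTTATGAAGATGGCATTTACGCCCGCGCAGAATCGT
AGAAGTACAGCAACGTCAGGAAGAATCCCTAAGCGCGTAGTTGGCCGTCGCACGATGCACCAATGATCTG
AATCTCTAGTTTTCAGTCCTACGACTACAATCCGCAATAGAATGGCGAACAGGCGGCGCCATAAGTTGAT
TGGTATTGGTTAACAAAATAGGTGTCTGGACGGGTTTATTGCATTCAGCCGCAAGAAACAAATTACTGTT
AACCACGTCTCGTTACATCGACGGGCTCTCGGAATCCGGACCAAGGCAATCTAGACACATTTGGCTTGGG
GTCTCTCTGGGCTTGGATTCCAAGCCCTATCACTAGTTTC
>Proctophyllodes_sp_M_ater_1
CCTGGTAATATGCACACTCCGTATTTTTGCGCAGCTACACGCGCTTTTGTTAATAAGTTGCGGATGTAGC
ATGCTATTTATTAGCTTGAGTGCTACTCTCATAGCATCTATGACCTGCCCTGCCGTAGGATATGTGCCAA
GCATATTATAGCTGGGAGTGTCATTAGAAATGTCTCAGAGGTGAGAGGTGGTCTCACGGAGAAAAGAACA
AGACGGTGGCGTGACTGTTCTCTCTTGCCGAACCTTTATGAAGATGGTATTTACGCCCGAGCAGAATCGT
AAAAGTGCAGCAACGCGAGGGAGAATCCCAAAGCACGTAGTTGGCGGTCGCACGATGCACCAATGATCTG
AATCTCTAGTTATCGGTCCTACGGCTACAATTCGCAATAGAATGGCGAACAGGCGGCGCCATAAGTTAAT
GGGTATTGCTTAACAAAATAGGTGTCTGGACGGGTTTATTGCATTCAGACGCAAGAAACAAATTGCTGTA
AACCACATCTCGTTACATCGACGGGCCCTCGGAACCCGGACCAAGGCAATCTAGACACCTTTGGCTTGGG
GTCTCTCTGGGCTTGGATTCCAGGCCCTATCACTAGTTTC
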