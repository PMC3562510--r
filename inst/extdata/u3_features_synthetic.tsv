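feature	sequence
repeat_1	TATGGAACGATTTGAAATGATGCGGAGTGA
unique_2	CAGCGATTTCCTCTGCTGTGAATG
repeat_4	GCGGGGCAACCGCAAACGCCA
repeat_5	ACGGGTATTCGGATAAACGGG
repeat_6	TTATCCCTTTTTCGAGACAAGTTC
tata	TATAAAAG
insertion_190	TTGGCCTGCAAAGAAATAAGGGGCCGATGGACCCTGCATATAAAGCGTTGATCCGGGGTCTTCTGTGGGCAGTGCGAAGACTGCAAGCAAGATTAAGAACGTCTCAGGTGCGAGTGAGGCTTCAGCGTGCAGTGACTTTTTAAGATTACTTCCACTAACACATTCAAATTGGTAGAGGCGTTTGGCCATG
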