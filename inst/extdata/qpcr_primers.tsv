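gene	forward	reverse
beta-actin	CTATGCTCTCCCTCACGCCA	TCACGCACGATTTCCCTCTC
Ptp4a3	CCTGTAAGGCAGCCCCAACTA	GTGTCTTAGCCAGGGTTTTATG
Samd4	CAGACGAGGAAGAGTAGAGGG	ACAGACGCATTACTATCACCAA
Ifitm3	GAGGACCAAGGTGCTGATGTT	TAGCCTATGCCTACTCCGTGAA
Gzmb	GCCAGTCTTTGCAGTCCTTTA	CTCTGATTACCCATCGTCCCT
Acta1	CCTTCTGACCCATACCTACCAT	AAGCCTCACTTCCTACCCTCG
Rbm45	TTTAGGTTCAGCCAAGAGTGC	CGGGAGAAGTTCAAGGTGTAT
Capn5	TGATTCCTCTTAGCCTCGTCA	GTGGATTTCACAGGTGGTGTT
Rps3a1	AGCAAGGCTCACTTCAAACAC	TTAGGAACATCGGGAAGACAC
Ipo4	AGCCACTCCTCCATGTCTTCC	CATCTTTGGGTTGGGCGTACT
Asb15	GAGCCTCAGCATAATCTCATC	TATACTTCGCCGTCTCCAATA
Rabgap1l	AGAGGCGGCTTAGTTGTTTGG	GCGGTCTACCTGTTGATTGCC
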