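gene_id	keep	annotation
Csf2ra	1	clear role in proliferation, migration, apoptosis or differentiation
Grb2	1	clear role in proliferation, migration, apoptosis or differentiation
Pik3ca	1	clear role in proliferation, migration, apoptosis or differentiation
Spred2	1	clear role in proliferation, migration, apoptosis or differentiation
Spred3	1	clear role in proliferation, migration, apoptosis or differentiation
Gzmb	1	clear role in proliferation, migration, apoptosis or differentiation
Lcp2	1	clear role in proliferation, migration, apoptosis or differentiation
Ctps	1	clear role in proliferation, migration, apoptosis or differentiation
Nt5c3b	1	clear role in proliferation, migration, apoptosis or differentiation
Txnrd1	1	clear role in proliferation, migration, apoptosis or differentiation
Bcl2a1c	1	clear role in proliferation, migration, apoptosis or differentiation
Jmjd1c	1	clear role in proliferation, migration, apoptosis or differentiation
Lyl1	1	clear role in proliferation, migration, apoptosis or differentiation
Ptp4a3	1	clear role in proliferation, migration, apoptosis or differentiation
Samd4	1	clear role in proliferation, migration, apoptosis or differentiation
Ifitm3	1	clear role in proliferation, migration, apoptosis or differentiation
Acta1	1	clear role in proliferation, migration, apoptosis or differentiation
Rbm45	1	clear role in proliferation, migration, apoptosis or differentiation
Capn5	1	clear role in proliferation, migration, apoptosis or differentiation
Rps3a1	1	clear role in proliferation, migration, apoptosis or differentiation
Ipo4	1	clear role in proliferation, migration, apoptosis or differentiation
Asb15	1	clear role in proliferation, migration, apoptosis or differentiation
Rabgap1l	1	clear role in proliferation, migration, apoptosis or differentiation
Olfr1120	0	no clear functional annotation
Hilpda	1	clear role in proliferation, migration, apoptosis or differentiation
Ebag9	0	no clear functional annotation
Rgs1	0	no clear functional annotation
Tmc1	0	no clear functional annotation
Snx33	0	no clear functional annotation
Snhg17	0	no clear functional annotation
Olfr1113	0	no clear functional annotation
Commd9	0	no clear functional annotation
Rhno1	0	no clear functional annotation
Foxm1	1	clear role in proliferation, migration, apoptosis or differentiation
Pgm5	0	no clear functional annotation
Mug1	0	no clear functional annotation
Zfp36l1	0	no clear functional annotation
Tmem131	0	no clear functional annotation
Fbxo21	0	no clear functional annotation
Dcaf11	0	no clear functional annotation
Ankrd13a	0	no clear functional annotation
Ccdc71l	0	no clear functional annotation
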