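gene_id
Csf2ra
Grb2
Pik3ca
Spred2
Spred3
Gzmb
Lcp2
Ctps
Nt5c3b
Txnrd1
Bcl2a1c
Jmjd1c
Lyl1
Ptp4a3
Samd4
Ifitm3
Acta1
Rbm45
Capn5
Rps3a1
Ipo4
Asb15
Rabgap1l
Olfr1120
Hilpda
Ebag9
Rgs1
Tmc1
Snx33
Snhg17
Olfr1113
Commd9
Rhno1
Foxm1
Pgm5
Mug1
Zfp36l1
Tmem131
Fbxo21
Dcaf11
Ankrd13a
Ccdc71l
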