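Jak-STAT signaling pathway	synthetic stand-in member list; total=155	CSF2RA	GRB2	PIK3CA	SPRED2	SPRED3	JAK1	JAK2	JAK3	TYK2	STAT1	STAT2	STAT3	STAT4	STAT5A	STAT5B	IL2RA	IL4RA	IL6ST	EPOR	MPL	SOCS1	SOCS3
Natural killer cell mediated cytotoxicity	synthetic stand-in member list; total=119	GRB2	GZMB	LCP2	PIK3CA	KLRK1	NCR1	PRF1	FASLG	ITGB2	SH2D1A	VAV1	ZAP70	KLRD1	FCGR4
Fc epsilon RI signaling pathway	synthetic stand-in member list; total=70	GRB2	LCP2	PIK3CA	FCER1A	FCER1G	SYK	LYN	FYN	PLCG1	MAP2K3	PRKCA	VAV1
Pyrimidine metabolism	synthetic stand-in member list; total=104	CTPS	NT5C3B	TXNRD1	POLR2A	POLR2B	POLD1	POLE	UMPS	CAD	DPYD	UPP1	NME1	TK1
T cell receptor signaling pathway	synthetic stand-in member list; total=105	GRB2	LCP2	PIK3CA	CD3E	CD3D	CD3G	CD28	LCK	ZAP70	PLCG1	NFATC1	PDCD1	CTLA4
Transcriptional misregulation in cancer	synthetic stand-in member list; total=178	BCL2A1C	GZMB	JMJD1C	LYL1	RUNX1	ETV6	MLLT3	KMT2A	PAX5	MEIS1	HOXA9	FLT3	IGF1R	CEBPA
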