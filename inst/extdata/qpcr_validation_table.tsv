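gene_id	fold_LB	stars_LB	fold_HB	stars_HB
Ptp4a3	0.11985	***	0.07554	***
Samd4	0.10351	***	0.04879	***
Ifitm3	0.39707	*	0.53172	
Gzmb	0.41548		0.35731	*
Acta1	0.06175	**	0.11185	*
Rbm45	0.70175		0.49878	**
Capn5	0.08935	***	0.06172	***
Rps3a1	0.48881	***	0.57754	**
Ipo4	0.39123	**	0.3192	**
Asb15	0.09352	**	0.256	
Rabgap1l	0.23461	***	0.41362	**
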