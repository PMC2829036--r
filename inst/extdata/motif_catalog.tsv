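motif_id	isoform	structural_type	mode	pattern	classes	window	min_fraction	min_run	min_repeats	terminus	terminal_window	variant
SUMO	A	all	pattern	ΨKxE	.	.	.	.	.	none	.	canonical
NLS	A	all	pattern	K(K/R)x(K/R)	.	.	.	.	.	none	.	canonical
NLS_VARIANT	A	type-4	pattern	KxxR	.	.	.	.	.	none	.	KxxR
DDW	A	all	pattern	(D/E)(D/E)W	.	.	.	.	.	none	.	canonical
ABOX	A	type-1	pattern	NGxSPSxxSSYDxxYSP	.	.	.	.	.	c_terminal	40	type-1
ABOX	A	type-2	pattern	NGYSSP(M/L)SSGSYDPYSP	.	.	.	.	.	c_terminal	40	type-2
ABOX	A	type-3	pattern	NGxPSPTMSSMSYDPYSP	.	.	.	.	.	c_terminal	40	type-3
ABOX	A	type-4	pattern	NGYASPMS(T/S)GSYDPYSP	.	.	.	.	.	c_terminal	40	type-4
ABOX	A	type-5	pattern	NGYASPMSAGSYDPYSPNG	.	.	.	.	.	c_terminal	40	type-5
DLKHE	A	type-2	pattern	DLKHE	.	.	.	.	.	n_terminal	25	canonical
PSIAYRG	A	type-2	pattern	ΨAYRG	.	.	.	.	.	n_terminal	25	canonical
DTS_REPEATS	A	type-4	repeat	D(T/S)S	.	.	.	.	2	n_terminal	25	canonical
YRLN	A	type-5	pattern	YRLN	.	.	.	.	.	n_terminal	10	canonical
KRRW	B1	all	pattern	(K/R)RRW	.	.	.	.	.	n_terminal	10	canonical
TXXPSIW	B1	type-2	pattern	TxxΨW	.	.	.	.	.	n_terminal	10	canonical
PRVPVAGV	B1	type-4	pattern	LQTVPRVPVAGV	.	.	.	.	.	n_terminal	25	type-4
PRVPVAGV	B1	type-5	pattern	LAVPRVPVAGV	.	.	.	.	.	n_terminal	25	type-5
SRICH	B1	all	hybrid	EV(T/S)SS	ACIDIC+NEUTRAL_POLAR	8	0.6	.	.	none	.	canonical
SRICH	B1	type-2p	hybrid	QVSSS	ACIDIC+NEUTRAL_POLAR	8	0.6	.	.	none	.	QVSSS
DLRICH	B1	all	composition	.	ACIDIC+BULKY	10	0.8	8	.	none	.	canonical
DLRICH	B1	type-6	pattern	(D/E)Y(C/G)(E/D)LWxxxxD	.	.	.	.	.	none	.	modified
SP	B1	all	context	SP	.	.	.	.	.	none	.	canonical
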