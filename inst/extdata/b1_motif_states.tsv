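taxon	TXXPSIW	KRRW	PRVPVAGV	SRICH	SP	DLRICH
Crustacea	0	0	0	1	1	1
Apterygota	0	0	0	1	1	1
Paleoptera	0	0	0	1	1	1
Polyneoptera	1	0	0	1	1	1
Psocodea	1	0	0	1	1	1
Heteroptera	1	0	0	1	0	1
Hymenoptera	0	1	1	1	1	1
Coleoptera	0	1	0	1	1	1
Neuropterida	0	1	0	1	1	1
Trichoptera	0	1	0	1	1	1
Lepidoptera	0	1	0	1	1	1
Mecoptera	0	1	1	1	1	1
Diptera	0	1	0	1	1	1
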