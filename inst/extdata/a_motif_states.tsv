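taxon	DLKHE	PSIAYRG	DTS_REPEATS	YRLN	SUMO	NLS	DDW	ABOX
Crustacea	0	0	0	0	1	1	1	1
Apterygota	?	?	?	?	?	?	?	?
Paleoptera	1	1	0	0	1	1	1	1
Polyneoptera	1	1	0	0	1	1	1	1
Psocodea	1	1	0	0	1	1	1	1
Heteroptera	0	0	0	0	0	0	1	1
Hymenoptera	0	0	1	0	1	1	1	1
Coleoptera	1	1	0	0	1	1	1	1
Neuropterida	1	1	0	0	1	1	1	1
Trichoptera	1	1	0	0	1	1	1	1
Lepidoptera	1	1	0	0	1	0	1	1
Mecoptera	0	0	1	0	1	1	1	1
Diptera	0	0	0	1	1	1	1	1
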