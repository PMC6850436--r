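relationship	r1	r0	kinship	nSites	seed
PO	0.498664	0.0000000	 0.249665677	5e+05	42
FS	0.668894	0.0744786	 0.248804610	5e+05	42
HS	0.338387	0.2013450	 0.125647573	5e+05	42
C1	0.278048	0.3357633	 0.062438694	5e+05	42
UR	0.227810	0.5017219	-0.000584902	5e+05	42
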