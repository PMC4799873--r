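# Xq28 microsatellite marker map flanking the F8 c.6046C>T mutation.
# Physical positions in Mb; recombination fractions are derived (1 Mb ~ 1 cM).
name	type	xq_band	position_mb	repeat_unit	allele_min	allele_max
DXS7423	marker	Xq28	149.71	TCCA	175	199
DXS1073	marker	Xq28	153.82	TG	120	146
STR24	marker	Xq28	154.07	GT	178	196
STR22	marker	Xq28	154.10	GT	198	210
c.6046C>T	mutation	Xq28	154.13	NA	NA	NA
STR13	marker	Xq28	154.16	TG	148	164
DXS1108	marker	Xq28	154.86	CA	160	177
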