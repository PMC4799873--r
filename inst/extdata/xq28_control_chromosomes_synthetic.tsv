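# Synthetic control chromosomes: 96 hemizygous haplotypes constructed to match
# the per-marker control allele counts observed in the study population
# (189:15, 128:16, 190:80, 206:63, 156:48, 171:29 of 96); the joint phase is
# synthetic and no control carries any of the disease haplotypes H1-H5.
sample_id	family_id	group	DXS7423	DXS1073	STR24	STR22	STR13	DXS1108
C001	CF001	control	175	120	190	206	148	165
C002	CF002	control	189	128	190	202	152	177
C003	CF003	control	189	124	190	206	152	171
C004	CF004	control	183	120	178	206	156	161
C005	CF005	control	175	124	190	198	152	161
C006	CF006	control	193	128	190	198	152	171
C007	CF007	control	175	136	190	206	148	177
C008	CF008	control	179	120	178	206	156	161
C009	CF009	control	183	124	190	206	156	161
C010	CF010	control	175	132	190	206	156	161
C011	CF011	control	179	124	186	206	148	161
C012	CF012	control	175	120	190	206	148	161
C013	CF013	control	175	128	190	206	156	177
C014	CF014	control	179	120	178	198	152	177
C015	CF015	control	193	120	190	198	152	171
C016	CF016	control	189	128	190	206	152	177
C017	CF017	control	175	124	190	202	148	177
C018	CF018	control	189	136	190	206	156	161
C019	CF019	control	179	132	190	202	156	161
C020	CF020	control	179	124	190	198	156	177
C021	CF021	control	193	120	190	206	148	161
C022	CF022	control	183	120	190	206	148	171
C023	CF023	control	175	128	190	206	156	171
C024	CF024	control	175	128	178	206	148	161
C025	CF025	control	179	124	190	206	156	161
C026	CF026	control	189	124	190	206	148	165
C027	CF027	control	175	132	190	206	152	161
C028	CF028	control	179	120	190	206	148	161
C029	CF029	control	175	132	190	206	156	165
C030	CF030	control	183	120	190	202	156	171
C031	CF031	control	179	120	178	206	152	165
C032	CF032	control	193	124	190	206	156	171
C033	CF033	control	179	124	178	202	152	165
C034	CF034	control	175	120	186	198	156	161
C035	CF035	control	189	120	190	206	152	171
C036	CF036	control	175	120	190	206	156	171
C037	CF037	control	175	136	190	206	156	165
C038	CF038	control	179	132	190	206	152	177
C039	CF039	control	175	124	190	206	156	161
C040	CF040	control	179	120	190	202	152	161
C041	CF041	control	179	132	190	206	156	171
C042	CF042	control	183	136	186	202	156	161
C043	CF043	control	189	120	190	198	148	171
C044	CF044	control	179	132	190	202	152	171
C045	CF045	control	175	128	190	206	156	171
C046	CF046	control	183	132	190	206	156	161
C047	CF047	control	175	128	190	198	148	165
C048	CF048	control	189	124	190	206	152	165
C049	CF049	control	183	120	190	206	156	177
C050	CF050	control	179	120	190	206	156	171
C051	CF051	control	179	124	190	206	148	165
C052	CF052	control	193	128	190	206	156	165
C053	CF053	control	175	120	190	206	148	161
C054	CF054	control	179	136	190	206	148	165
C055	CF055	control	189	124	190	206	148	161
C056	CF056	control	183	124	186	198	156	165
C057	CF057	control	175	124	190	206	156	171
C058	CF058	control	183	132	190	206	156	171
C059	CF059	control	193	124	190	198	156	165
C060	CF060	control	175	120	190	206	152	165
C061	CF061	control	183	124	190	198	156	177
C062	CF062	control	179	132	190	198	156	161
C063	CF063	control	179	124	190	206	156	177
C064	CF064	control	193	136	178	206	156	177
C065	CF065	control	179	120	190	202	156	165
C066	CF066	control	183	136	190	206	156	161
C067	CF067	control	183	136	186	206	152	171
C068	CF068	control	189	136	190	202	152	161
C069	CF069	control	179	120	190	202	156	177
C070	CF070	control	175	128	190	202	152	171
C071	CF071	control	189	124	190	198	148	161
C072	CF072	control	189	124	190	206	156	161
C073	CF073	control	175	120	190	206	148	171
C074	CF074	control	175	132	190	198	148	171
C075	CF075	control	175	120	190	206	148	177
C076	CF076	control	193	120	190	202	156	171
C077	CF077	control	175	120	190	198	156	165
C078	CF078	control	175	120	186	206	152	161
C079	CF079	control	183	128	190	206	148	177
C080	CF080	control	183	124	190	206	156	165
C081	CF081	control	189	132	186	206	156	165
C082	CF082	control	183	124	190	202	156	177
C083	CF083	control	175	128	190	206	152	165
C084	CF084	control	175	128	190	206	152	171
C085	CF085	control	189	120	190	206	152	171
C086	CF086	control	175	128	186	206	156	171
C087	CF087	control	193	132	190	202	156	171
C088	CF088	control	175	128	190	198	156	171
C089	CF089	control	179	124	178	206	156	171
C090	CF090	control	189	132	190	206	148	171
C091	CF091	control	179	120	190	206	152	165
C092	CF092	control	179	120	190	206	156	161
C093	CF093	control	193	124	190	206	148	161
C094	CF094	control	179	132	190	206	156	177
C095	CF095	control	183	136	190	202	148	161
C096	CF096	control	179	128	190	198	156	171
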