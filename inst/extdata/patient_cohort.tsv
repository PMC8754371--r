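patient	sex	age	handedness	seizure_onset_age	n_aed	epileptogenic_zone	stai
1	M	25	L	10	3	R posttemporal	36
2	F	24	R	5	2	R temporooccipital	32
3	F	22	R	8	3	R basal temporal	29
8	F	28	R	24	2	R temporopolar and amygdalohippocampal	40
10	M	25	R	15	4	R temporooccipital	NA
12	M	20	R	16	2	L basal temporal	21
14	M	48	R	22	2	R temporolateral and multifocal	38
15	M	37	L	1	3	R post- and lateral occipital	26
16	F	44	R	19	2	R basal temporal	35
17	M	31	R	12	3	R postsuperior temporal	26
18	F	31	R	26	2	L temporal periventricular	28
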