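group	category	n	pct_published
sex	female	136	48.2
sex	male	132	46.8
sex	unknown	14	5.0
age	0-11	28	9.9
age	12-17	37	13.1
age	18-34	16	5.7
age	35-64	63	22.3
age	65-79	9	3.3
age	>=80	2	0.7
age	unknown	127	45.0
outcome	death	6	2.1
outcome	disability	2	0.7
outcome	hospitalization	48	17.0
outcome	life_threatening	6	2.1
outcome	unknown	15	5.3
outcome	other	205	72.7
country	United States	72	25.5
country	United Kingdom	71	25.2
country	Canada	42	14.9
country	Colombia	13	4.6
country	Turkey	11	3.9
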