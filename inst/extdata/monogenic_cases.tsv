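gene	variant_type	age_at_diagnosis_years	consanguineous	grs	t1d_centile
WFS1	frameshift	1.99	no	7.002	1
WFS1	missense	4	first_cousin	9.101	13.8
WFS1	missense	2.47	first_cousin	8.824	11.3
SLC19A2	nonsense	5	first_cousin	9.135	14.6
SLC29A3	frameshift	4.42	third_cousin	8.004	4.1
GCK	splicing	0.75	no	8.151	5.7
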