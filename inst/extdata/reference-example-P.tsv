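state	PA	RW	LW	TW	CA
PA	0.667	0.067	0.044	0.089	0.133
RW	0.167	0	0.5	0.167	0.167
LW	0.2	0.05	0.5	0.2	0.05
TW	0.111	0	0.133	0.667	0.089
CA	0.154	0.077	0	0.231	0.538
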