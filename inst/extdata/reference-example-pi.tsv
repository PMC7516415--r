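state	pi
PA	0.310
RW	0.042
LW	0.148
TW	0.317
CA	0.183
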