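metabolite	R_in	B1	B2	B3	B4	B5	R_out
reversible	0	0	0	0	0	0	0
A	1	-1	-1	-1	-1	-1	0
B	0	1	1	1	1	1	-1
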