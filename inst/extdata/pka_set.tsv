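group	pka	sign
nterm	9.0	1
cterm	2.0	-1
D	3.9	-1
E	4.1	-1
C	8.3	-1
Y	10.1	-1
H	6.0	1
K	10.5	1
R	12.5	1
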