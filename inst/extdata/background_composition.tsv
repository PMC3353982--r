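residue	percent	release_tag
A	8.25	swissprot_2010_emulated
C	1.37	swissprot_2010_emulated
D	5.45	swissprot_2010_emulated
E	6.75	swissprot_2010_emulated
F	3.86	swissprot_2010_emulated
G	7.07	swissprot_2010_emulated
H	2.27	swissprot_2010_emulated
I	5.96	swissprot_2010_emulated
K	5.84	swissprot_2010_emulated
L	9.66	swissprot_2010_emulated
M	2.42	swissprot_2010_emulated
N	4.06	swissprot_2010_emulated
P	4.70	swissprot_2010_emulated
Q	3.93	swissprot_2010_emulated
R	5.53	swissprot_2010_emulated
S	6.56	swissprot_2010_emulated
T	5.34	swissprot_2010_emulated
V	6.87	swissprot_2010_emulated
W	1.08	swissprot_2010_emulated
Y	2.92	swissprot_2010_emulated
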