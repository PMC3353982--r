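residue	kyte_doolittle	hopp_woods	eisenberg	bulkiness_zimmerman	flexibility_bhaskaran	janin_accessible	janin_buried	zhao_london_tm
A	1.8	-0.5	0.62	11.50	0.357	6.6	11.2	0.38
C	2.5	-1.0	0.29	13.46	0.346	0.9	4.1	-0.30
D	-3.5	3.0	-0.90	11.68	0.511	7.7	2.9	-3.27
E	-3.5	3.0	-0.74	13.57	0.497	5.7	1.8	-2.90
F	2.8	-2.5	1.19	19.80	0.314	2.4	5.1	1.98
G	-0.4	0.0	0.48	3.40	0.544	6.7	11.8	-0.19
H	-3.2	-0.5	-0.40	13.69	0.323	2.5	2.0	-1.44
I	4.5	-1.8	1.38	21.40	0.462	2.8	8.6	1.97
K	-3.9	3.0	-1.50	15.71	0.466	10.3	0.5	-3.46
L	3.8	-1.8	1.06	21.40	0.365	4.8	11.7	1.82
M	1.9	-1.3	0.64	16.25	0.295	1.0	1.9	1.40
N	-3.5	0.2	-0.78	12.82	0.463	6.7	2.9	-1.62
P	-1.6	0.0	0.12	17.43	0.509	4.8	2.7	-1.44
Q	-3.5	0.2	-0.85	14.45	0.493	5.2	1.6	-1.84
R	-4.5	3.0	-2.53	14.28	0.529	4.5	0.5	-2.57
S	-0.8	0.3	-0.18	9.47	0.507	9.4	8.0	-0.53
T	-0.7	-0.4	-0.05	15.77	0.444	7.0	4.9	-0.32
V	4.2	-1.5	1.08	21.57	0.386	4.5	12.9	1.46
W	-0.9	-3.4	0.81	21.67	0.305	1.4	2.2	1.53
Y	-1.3	-2.3	0.26	18.03	0.420	5.1	2.6	0.49
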