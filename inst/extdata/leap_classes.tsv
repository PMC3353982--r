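class_id	pfam_acc	pattern	n_sequences	len_min	len_max	consensus_total_chars	consensus_gap_number
1	PF00257	[GS]SSE.[DEG]	145	117	507	790	680
2	PF00257	S{5,}[ADGV][DES][DEGKT].	65	140	292	478	338
3	PF00257	DSD$	20	86	179	219	129
4	PF00257	STTAPGHY|HKTGTTTS|GGGGIGTG|HS[DR]N?K$|DVE$|LH(TRASHEES)?$|C?TGH$|DKLPGQH$|QQN(KTGCD)?$|RGD$|KEGY$|GHRPQI$|GHNN$|SFKS$|GTHKGL$|SSRDNY$|GQSK$|HRDV$|NDL$	63	83	616	724	664
5	PF00477	G[AG][ENQT].R[AKR][DEQ]	58	83	217	235	145
6	PF02987	[^LNP][^G][ADEGILMQRSTVY][AEKQRSTY].[KR][AT].[ADENT][^DP][EGIKLMQST].{1,67}[^DER][^AS]K[AD][^IL][^N].[^E]?.{1,6}G?	125	67	742	847	767
7	PF03168	NPY.{4,}P[IV].[ADEQ]	30	95	181	212	72
8	PF03168	[AILV].{0,1}NPN.[FIRSVY]	35	153	368	440	329
9	PF03242	W.{1,3}DP.{1,3}G	64	78	144	191	134
10	PF03760	[AS].{3,3}[EG][HK].[DE].{3,3}[AT].{4,4}[DEKQ].{3,3}[AT]	68	88	173	195	68
11	PF04927	(T.GEAL[EH]A)|(PGGVA)	20	159	278	307	133
12	PF10714	[HY]K.{2,2}[AG]Y	17	71	117	124	58
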