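alignment_id	position	arctic_aa	temperate_aa	annotation	functional_group
9895	384	N	D,F,K,T	Methylation of tRNAs	J
1375	52	S	A,D,P,V	Zinc finger, C3HC4 type	K
2720	413	N	Q,S	Zinc finger, Nab2-type	K
6123	30	A,I	V	Sec23/Sec24 zinc finger	K
2998	749	E	C,G,I,Q,R,S,T	DNA mismatch repair protein Mlh1	L
7630	448	E	K,Q,S	DNA polymerase alpha/epsilon subunit B	L
7700	423	V	E,G,S,T	Sugar transporter	G
5037	269	Q	E,K,R	Membrane-bound acyltransferase	I
5781	218	K	E,G,S,V	Oxidation-reduction (dehydrogenase)	I,Q
6653	168	E	D,G,Q	All-trans-retinol 13,14-reductase	I,Q
8045	893	S	A,V	ABC transporter	Q
8045	1162	V	A,I
8045	1259	A	I,K,V
631	616	W	A,F,H,L,Y	Chitinase class I	R
557	16	L	A,F,I,S,T	—	S
908	158	D,F,T	S	—	S
2702	371	C	F,S,Y	—	S
2993	141	S	A,E,H,K,Q,R	—	S
3485	150	S	A,D,E,T	—	S
4072	662	M	A,G,L,P,S,T,V	—	S
4756	49	A	E,N,T,V	—	S
4990	33	E	A,D,K,N,Q,S,T,V	—	S
6457	27	A	K,P,S	—	S
10130	156	N	D,F,G,L,S	—	S
11282	276	N	K,L,R,V	—	S
11341	215	M	I,K,L,S	—	S
12554	333	L	V	—	S
13375	292	A,F,I	V	—	S
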