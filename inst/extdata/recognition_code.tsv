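position	residue	pA	pC	pG	pT
-1	R	0.05	0.05	0.85	0.05
-1	K	0.05	0.05	0.05	0.85
-1	Q	0.85	0.05	0.05	0.05
-1	N	0.85	0.05	0.05	0.05
-1	D	0.05	0.85	0.05	0.05
-1	E	0.05	0.85	0.05	0.05
-1	T	0.85	0.05	0.05	0.05
-1	H	0.05	0.05	0.85	0.05
2	D	0.05	0.85	0.05	0.05
2	E	0.05	0.85	0.05	0.05
2	S	0.85	0.05	0.05	0.05
2	T	0.85	0.05	0.05	0.05
2	R	0.05	0.05	0.85	0.05
2	K	0.05	0.05	0.85	0.05
3	E	0.05	0.85	0.05	0.05
3	D	0.05	0.85	0.05	0.05
3	H	0.05	0.05	0.85	0.05
3	N	0.85	0.05	0.05	0.05
3	T	0.05	0.05	0.05	0.85
3	S	0.05	0.05	0.05	0.85
3	K	0.05	0.05	0.85	0.05
3	R	0.05	0.05	0.85	0.05
6	R	0.05	0.05	0.85	0.05
6	K	0.05	0.05	0.85	0.05
6	Q	0.85	0.05	0.05	0.05
6	E	0.05	0.85	0.05	0.05
6	T	0.05	0.05	0.05	0.85
6	H	0.05	0.05	0.85	0.05
6	N	0.85	0.05	0.05	0.05
6	D	0.05	0.85	0.05	0.05
6	S	0.05	0.05	0.05	0.85
6	V	0.85	0.05	0.05	0.05
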