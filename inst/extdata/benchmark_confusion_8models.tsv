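# Confusion counts for the eight k-of-5 consensus voting models evaluated on
# the 100-variant clinically labeled standard set (50 pathogenic / 50 benign
# breast-cancer nsSNPs from ClinVar). Models A-D require at least 1-4 of the
# five functional predictors to call the variant significant; A3-D3 add
# conservation and stability gates.
model	tp	fn	tn	fp
A	50	0	25	25
B	46	4	32	18
C	45	5	40	10
D	42	8	47	3
A3	48	2	40	10
B3	44	6	44	6
C3	39	11	46	4
D3	38	12	48	2
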