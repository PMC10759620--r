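branch	N_sites	S_sites	Nd	Sd	pN	pS	omega	fisher_p	flag
anc->echidna	269.916666666667	90.0833333333333	1	0	0.00370484717505403	0	NA	1	pS_zero
anc->platypus	269.333333333333	90.6666666666667	2.5	1.5	0.00928217821782178	0.0165441176470588	0.561056105610561	0.371591616494061	ok
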