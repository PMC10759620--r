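site,from_residue,to_residue,shift_nm
180,S,A,-5
180,A,S,5
197,H,Y,-28
197,Y,H,28
277,Y,F,-8
277,F,Y,8
285,T,A,-15
285,A,T,15
308,A,S,-27
308,S,A,27
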