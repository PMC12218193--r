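essround,anweight,prtclde,prtdgcl,wrclmch,ccnthum
8,1.0,1,2,4,4
8,0.8,66,,3,3
8,1.2,2,4,5,4
8,1.0,9,2,2,3
8,1.0,77,,3,2
8,1.0,4,1,8,3
8,1.0,3,2,4,55
8,0.9,6,3,1,2
10,1.0,1,2,4,5
10,1.1,66,,2,3
10,1.0,2,2,3,4
10,1.0,4,3,5,5
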