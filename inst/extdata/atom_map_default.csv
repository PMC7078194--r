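metabolite,element,positions,source
glutamine,C,5,gln_backbone
glutamine,N,1,gln_amide
glutamine,N,1,gln_amine
glutamate,C,5,gln_backbone
glutamate,N,1,gln_amine
aKG,C,5,gln_backbone
fumarate,C,4,gln_backbone
aspartate,C,4,unlabeled
aspartate,N,1,aspartate
IMP,C,5,glucose
IMP,N,2,gln_amide
IMP,N,1,aspartate
IMP,N,1,unlabeled
AMP,C,5,glucose
AMP,N,2,gln_amide
AMP,N,2,aspartate
AMP,N,1,unlabeled
GMP,C,5,glucose
GMP,N,3,gln_amide
GMP,N,1,aspartate
GMP,N,1,unlabeled
UMP,C,5,glucose
UMP,N,1,gln_amide
UMP,N,1,aspartate
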