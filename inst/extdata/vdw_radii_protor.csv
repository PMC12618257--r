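element,radius
H,1.09
C,1.88
N,1.64
O,1.46
S,1.77
P,1.80
SE,1.90
MG,1.73
NA,2.27
K,2.75
CL,1.75
CA,1.74
FE,1.40
ZN,1.39
MN,1.39
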