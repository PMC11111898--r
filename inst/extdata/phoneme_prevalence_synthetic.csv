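phoneme,weight
AA,1.5
AE,2.5
AH,11.0
AO,1.2
AW,0.6
AY,1.5
B,1.8
CH,0.5
D,4.0
DH,3.0
EH,2.7
ER,2.0
EY,1.4
F,1.8
G,1.2
HH,1.8
IH,6.0
IY,2.4
JH,0.5
K,3.0
L,4.0
M,2.8
N,7.0
NG,1.0
OW,1.3
OY,0.1
P,1.8
R,6.0
S,4.6
SH,0.8
T,7.0
TH,0.4
UH,0.4
UW,1.5
V,2.0
W,2.0
Y,0.8
Z,2.7
ZH,0.1
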