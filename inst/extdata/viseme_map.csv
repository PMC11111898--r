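phoneme,viseme
P,bilabial
B,bilabial
M,bilabial
F,labiodental
V,labiodental
TH,dental
DH,dental
T,alveolar
D,alveolar
S,alveolar
Z,alveolar
N,alveolar
L,alveolar
SH,postalveolar
ZH,postalveolar
CH,postalveolar
JH,postalveolar
K,velar
G,velar
NG,velar
HH,glottal
R,rhotic
ER,rhotic
W,rounded_glide
Y,palatal_glide
AO,rounded_vowel
OW,rounded_vowel
UH,rounded_vowel
UW,rounded_vowel
OY,rounded_vowel
AW,rounded_vowel
AA,open_vowel
AE,open_vowel
AH,open_vowel
AY,open_vowel
EH,front_vowel
EY,front_vowel
IH,front_vowel
IY,front_vowel
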