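country,region
US,NorthAmerica
CA,NorthAmerica
MX,NorthAmerica
BR,SouthAmerica
AR,SouthAmerica
CL,SouthAmerica
CO,SouthAmerica
PE,SouthAmerica
GB,Europe
DE,Europe
FR,Europe
IT,Europe
ES,Europe
NL,Europe
BE,Europe
CH,Europe
AT,Europe
SE,Europe
NO,Europe
DK,Europe
FI,Europe
IE,Europe
PT,Europe
GR,Europe
PL,Europe
CZ,Europe
HU,Europe
RO,Europe
RU,Europe
UA,Europe
TR,Europe
JP,Asia
CN,Asia
KR,Asia
TW,Asia
HK,Asia
SG,Asia
TH,Asia
VN,Asia
MY,Asia
PH,Asia
ID,Asia
IN,Asia
PK,Asia
BD,Asia
IL,Asia
SA,Asia
AE,Asia
IR,Asia
IQ,Asia
AU,Oceania
NZ,Oceania
ZA,Africa
EG,Africa
NG,Africa
KE,Africa
MA,Africa
TN,Africa
DZ,Africa
GH,Africa
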