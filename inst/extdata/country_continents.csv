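country,continent,super_region
AD,Europe,
AL,Europe,
AT,Europe,
BA,Europe,
BE,Europe,
BG,Europe,
BY,Europe,
CH,Europe,
CY,Europe,
CZ,Europe,
DE,Europe,
DK,Europe,
EE,Europe,
ES,Europe,
FI,Europe,
FR,Europe,
GB,Europe,
GR,Europe,
HR,Europe,
HU,Europe,
IE,Europe,
IS,Europe,
IT,Europe,
LI,Europe,
LT,Europe,
LU,Europe,
LV,Europe,
MC,Europe,
MD,Europe,
ME,Europe,
MK,Europe,
MT,Europe,
NL,Europe,
NO,Europe,
PL,Europe,
PT,Europe,
RO,Europe,
RS,Europe,
RU,Europe,
SE,Europe,
SI,Europe,
SK,Europe,
SM,Europe,
UA,Europe,
DZ,Africa,
AO,Africa,
BJ,Africa,
BW,Africa,
BF,Africa,
BI,Africa,
CM,Africa,
CV,Africa,
CF,Africa,
TD,Africa,
KM,Africa,
CG,Africa,
CD,Africa,
CI,Africa,
DJ,Africa,
EG,Africa,
GQ,Africa,
ER,Africa,
ET,Africa,
GA,Africa,
GM,Africa,
GH,Africa,
GN,Africa,
GW,Africa,
KE,Africa,
LS,Africa,
LR,Africa,
LY,Africa,
MG,Africa,
MW,Africa,
ML,Africa,
MR,Africa,
MU,Africa,
MA,Africa,
MZ,Africa,
NA,Africa,
NE,Africa,
NG,Africa,
RW,Africa,
ST,Africa,
SN,Africa,
SC,Africa,
SL,Africa,
SO,Africa,
ZA,Africa,
SS,Africa,
SD,Africa,
SZ,Africa,
TZ,Africa,
TG,Africa,
TN,Africa,
UG,Africa,
ZM,Africa,
ZW,Africa,
AF,Asia,
AM,Asia,
AZ,Asia,
BH,Asia,
BD,Asia,
BT,Asia,
BN,Asia,
KH,Asia,
CN,Asia,
GE,Asia,
IN,Asia,
ID,Asia,
IR,Asia,
IQ,Asia,
IL,Asia,
JO,Asia,
JP,Asia,
KZ,Asia,
KW,Asia,
KG,Asia,
LA,Asia,
LB,Asia,
MY,Asia,
MV,Asia,
MN,Asia,
MM,Asia,
NP,Asia,
KP,Asia,
KR,Asia,
OM,Asia,
PK,Asia,
PS,Asia,
PH,Asia,
QA,Asia,
SA,Asia,
SG,Asia,
LK,Asia,
SY,Asia,
TW,Asia,
TJ,Asia,
TH,Asia,
TL,Asia,
TR,Asia,
TM,Asia,
AE,Asia,
UZ,Asia,
VN,Asia,
YE,Asia,
AG,North America,America
BS,North America,America
BB,North America,America
BZ,North America,America
CA,North America,America
CR,North America,America
CU,North America,America
DM,North America,America
DO,North America,America
SV,North America,America
GD,North America,America
GT,North America,America
HT,North America,America
HN,North America,America
JM,North America,America
MX,North America,America
NI,North America,America
PA,North America,America
KN,North America,America
LC,North America,America
VC,North America,America
TT,North America,America
US,North America,America
AR,South America,America
BO,South America,America
BR,South America,America
CL,South America,America
CO,South America,America
EC,South America,America
GY,South America,America
PY,South America,America
PE,South America,America
SR,South America,America
UY,South America,America
VE,South America,America
AU,Oceania,
FJ,Oceania,
KI,Oceania,
MH,Oceania,
FM,Oceania,
NR,Oceania,
NZ,Oceania,
PW,Oceania,
PG,Oceania,
WS,Oceania,
SB,Oceania,
TO,Oceania,
TV,Oceania,
VU,Oceania,
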