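country,sids,income
NZ,FALSE,high
AU,FALSE,high
GB,FALSE,high
US,FALSE,high
FR,FALSE,high
MX,FALSE,upper_middle
SC,TRUE,high
EC,FALSE,upper_middle
FJ,TRUE,upper_middle
TO,TRUE,upper_middle
KI,TRUE,lower_middle
PW,TRUE,high
MU,TRUE,upper_middle
MV,TRUE,upper_middle
BS,TRUE,high
CU,TRUE,upper_middle
DO,TRUE,upper_middle
WS,TRUE,lower_middle
VU,TRUE,lower_middle
SB,TRUE,lower_middle
PG,TRUE,lower_middle
JP,FALSE,high
CA,FALSE,high
IT,FALSE,high
ES,FALSE,high
PT,FALSE,high
ZA,FALSE,upper_middle
NO,FALSE,high
IS,FALSE,high
IE,FALSE,high
CL,FALSE,high
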