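uf,factor
AC,1.22
AL,1.18
AM,1.20
AP,1.21
BA,1.17
CE,1.16
DF,1.03
ES,1.06
GO,1.07
MA,1.25
MG,1.06
MS,1.08
MT,1.09
PA,1.23
PB,1.15
PE,1.14
PI,1.24
PR,1.04
RJ,1.05
RN,1.13
RO,1.19
RR,1.26
RS,1.03
SC,1.02
SE,1.12
SP,1.02
TO,1.21
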