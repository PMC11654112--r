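range_start,range_end,category
V01,V049,TRANSPORT_INJURY
V06,V809,TRANSPORT_INJURY
V82,V829,TRANSPORT_INJURY
V870,V879,TRANSPORT_INJURY
V89,V899,TRANSPORT_INJURY
V05,V059,OTHER_TRANSPORT
V81,V819,OTHER_TRANSPORT
V83,V869,OTHER_TRANSPORT
V880,V889,OTHER_TRANSPORT
V90,V99,OTHER_TRANSPORT
W00,W199,FALLS
X60,X649,SUICIDE
X66,X849,SUICIDE
Y870,Y870,SUICIDE
X85,Y099,HOMICIDE
Y871,Y871,HOMICIDE
W200,W469,OTHER_EXTERNAL
W490,W609,OTHER_EXTERNAL
W64,W709,OTHER_EXTERNAL
W730,W749,OTHER_EXTERNAL
W770,W779,OTHER_EXTERNAL
W810,W829,OTHER_EXTERNAL
W850,W949,OTHER_EXTERNAL
W979,W979,OTHER_EXTERNAL
W990,X069,OTHER_EXTERNAL
X08,X399,OTHER_EXTERNAL
X460,X489,OTHER_EXTERNAL
X50,X549,OTHER_EXTERNAL
X57,X589,OTHER_EXTERNAL
Y350,Y849,OTHER_EXTERNAL
Y880,Y883,OTHER_EXTERNAL
Y890,Y891,OTHER_EXTERNAL
L550,L558,OTHER_EXTERNAL
L563,L563,OTHER_EXTERNAL
L568,L568,OTHER_EXTERNAL
L580,L580,OTHER_EXTERNAL
L581,L581,OTHER_EXTERNAL
X59,X599,GC_INVESTIGATION
Y34,Y349,GC_INVESTIGATION
X450,X459,EXCLUDED_NCD
X650,X659,EXCLUDED_NCD
Y150,Y159,EXCLUDED_NCD
W750,W759,EXCLUDED_NEONATAL_ASPIRATION
W780,W809,EXCLUDED_NEONATAL_ASPIRATION
W830,W849,EXCLUDED_NEONATAL_ASPIRATION
G443,G443,GC_PROPORTIONAL
G913,G913,GC_PROPORTIONAL
R58,R589,GC_PROPORTIONAL
A40,A419,GC_NATURAL
R00,R999,GC_NATURAL
J12,J189,PNEUMONIA_TARGET
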