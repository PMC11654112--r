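garbage,destination,fraction
X59,FALLS,0.45
X59,TRANSPORT_INJURY,0.10
X59,OTHER_EXTERNAL,0.15
X59,HOMICIDE,0.05
X59,SUICIDE,0.02
X59,OTHER_TRANSPORT,0.03
X59,NATURAL_RESIDUAL,0.20
Y34,HOMICIDE,0.39
Y34,SUICIDE,0.11
Y34,TRANSPORT_INJURY,0.14
Y34,FALLS,0.08
Y34,OTHER_EXTERNAL,0.10
Y34,OTHER_TRANSPORT,0.03
Y34,NATURAL_RESIDUAL,0.15
PNEUMONIA_TARGET,PNEUMONIA_TARGET,0.70
PNEUMONIA_TARGET,FALLS,0.18
PNEUMONIA_TARGET,OTHER_EXTERNAL,0.07
PNEUMONIA_TARGET,TRANSPORT_INJURY,0.05
GC_NATURAL,NATURAL_RESIDUAL,0.90
GC_NATURAL,HOMICIDE,0.04
GC_NATURAL,TRANSPORT_INJURY,0.03
GC_NATURAL,FALLS,0.02
GC_NATURAL,OTHER_EXTERNAL,0.01
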