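recording,volunteer_1,volunteer_2,volunteer_3,volunteer_4,volunteer_5
K-FLEX-FR-1,o,x,o,o,o
K-FLEX-FR-2,o,x,o,o,o
K-FLEX-IN-1,o,o,o,o,x
K-FLEX-IN-2,o,o,o,o,o
H-ABD-FR-1,o,o,x,o,o
H-ABD-FR-2,o,o,o,o,o
H-ABD-IN-1,o,x,o,o,x
H-ABD-IN-2,o,x,o,o,o
H-FLE-FR-1,o,o,o,o,o
H-FLE-FR-2,o,o,x,o,o
H-FLEX-IN-1,x,o,o,o,o
H-FLEX-IN-2,x,o,o,x,o
E-FLEX-FR-1,o,o,o,o,x
E-FLEX-FR-2,o,o,o,o,o
E-FLEX-IN-1,o,o,o,x,o
E-FLEX-IN-2,x,o,o,o,x
S-ABD-FR-1,x,o,o,x,o
S-ABD-FR-2,o,x,o,o,o
S-ABD-IN-1,o,o,o,o,o
S-ABD-IN-2,x,o,o,o,o
S-FLEX-FR-1,o,o,o,o,o
S-FLEX-FR-2,o,o,o,o,o
S-FLEX-IN-1,o,o,o,o,o
S-FLEX-IN-2,o,o,o,o,o
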