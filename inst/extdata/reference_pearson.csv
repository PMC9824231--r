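movement,limb,astra,intel,kinect,mediapipe
K-FLEX-FR,lower,0.31,0.83,0.83,0.89
K-FLEX-IN,lower,0.51,0.69,0.81,0.86
H-ABD-FR,lower,0.54,0.26,0.82,0.69
H-ABD-IN,lower,0.7,0.37,0.91,0.66
H-FLEX-FR,lower,0.68,0.49,0.91,0.87
H-FLEX-IN,lower,0.71,0.41,0.69,0.84
E-FLEX-FR,upper,0.60,0.63,0.83,0.78
E-FLEX-IN,upper,0.73,0.87,0.93,0.85
S-ABD-FR,upper,0.91,0.87,0.96,0.97
S-ABD-IN,upper,0.84,0.90,0.96,0.96
S-FLEX-FR,upper,0.73,0.81,0.91,0.96
S-FLEX-IN,upper,0.82,0.76,0.94,0.95
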