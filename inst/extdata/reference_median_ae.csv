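movement,limb,astra,intel,kinect,mediapipe
K-FLEX-FR,lower,14.34,7.3,10.74,6.74
K-FLEX-IN,lower,11.3,10.26,11.38,8.56
H-ABD-FR,lower,5.39,8.08,8.86,5.63
H-ABD-IN,lower,8.79,7.79,10.89,6.03
H-FLEX-FR,lower,11.97,15.46,4.29,7.67
H-FLEX-IN,lower,13.22,20.5,9.64,8.31
E-FLEX-FR,upper,17.31,17.23,10.26,13.56
E-FLEX-IN,upper,11.6,9.7,11.13,15.92
S-ABD-FR,upper,7.5,8.3,9.6,8.17
S-ABD-IN,upper,7.8,7.9,18.59,7.97
S-FLEX-FR,upper,13.88,13.58,20.31,7.47
S-FLEX-IN,upper,16.39,13.18,26.15,6.81
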