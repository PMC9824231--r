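movement,limb,astra,intel,kinect,mediapipe
E-FLEX-FR,upper,30.24,28.20,21.55,22.49
E-FLEX-IN,upper,22.65,16.86,15.21,21.87
S-ABD-FR,upper,13.05,14.98,11.56,10.94
S-ABD-IN,upper,16.61,13.17,19.11,13.87
S-FLEX-FR,upper,25.56,23.26,22.43,12.19
S-FLEX-IN,upper,26.34,24.66,27.68,17.33
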