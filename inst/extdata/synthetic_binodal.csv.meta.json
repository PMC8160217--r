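{"coefficients":[0.3555,-5.22,0,-18.3],"validity_range":[0.001,0.5],"tie_slope":-0.55,"noise_level":0,"seed":1}
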