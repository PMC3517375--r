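sex,age_min,age_max,wage
F,18,24,22.21
F,25,34,28.60
F,35,44,31.90
F,45,54,33.40
F,55,64,32.10
M,18,24,24.80
M,25,34,34.70
M,35,44,43.20
M,45,54,52.91
M,55,64,49.60
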