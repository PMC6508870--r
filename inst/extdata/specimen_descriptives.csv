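specimen,mass_kg,height_m,included
S1,0.378,0.203,TRUE
S2,0.444,0.215,TRUE
S3,0.396,0.202,TRUE
S4,0.375,0.199,TRUE
S5,0.358,0.202,TRUE
S6,0.570,0.223,FALSE
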