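t,p1,p2,p3,p4,p5
60,0.089,0.442,0.415,0.052,0.002
61,0.063,0.376,0.484,0.073,0.003
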