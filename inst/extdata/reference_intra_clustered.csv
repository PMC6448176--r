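patient,clustered,precision,recall,f_measure
P1,0.33,0.78,1.00,0.88
P2,0.40,0.91,0.78,0.84
P3,0.32,0.84,0.81,0.82
P4,0.13,1.00,1.00,1.00
P5,0.41,0.59,0.93,0.72
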