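patient,coded,precision,recall,f_measure
P1,1.00,0.76,1.00,0.86
P2,0.99,0.85,0.99,0.91
P3,0.99,0.75,1.00,0.86
P4,1.00,0.78,1.00,0.88
P5,0.99,0.70,1.00,0.82
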