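patient,coded,precision,recall,f_measure
P1,0.67,0.93,0.74,0.83
P2,0.60,0.90,0.61,0.73
P3,0.68,0.73,0.69,0.71
P4,0.87,0.91,0.87,0.89
P5,0.59,0.80,0.63,0.70
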