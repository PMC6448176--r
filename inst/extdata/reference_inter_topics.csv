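patient,list_items,unique_items,topics
P1,302,184,61
P2,250,174,65
P3,861,441,118
P4,531,295,82
P5,378,262,91
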