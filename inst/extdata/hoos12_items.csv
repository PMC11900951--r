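hoos_item_id,scale
P4,pain
P5,pain
P6,pain
P8,pain
A2,function
A4,function
A10,function
A16,function
Q1,qol
Q2,qol
Q3,qol
Q4,qol
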