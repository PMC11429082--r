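misread,intended,weight,context
S,5,5,cm_adjacent
S,5,4,in_numeric_field
I,1,3,in_numeric_field
Z,2,2,in_numeric_field
b,6,1,in_numeric_field
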