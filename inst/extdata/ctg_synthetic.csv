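patient,A,B,C,D,E
P01,1,1,1,1,1
P02,1,1,1,1,1
P03,1,1,1,1,1
P04,1,1,1,1,1
P05,1,1,1,1,0
P06,0,1,1,1,0
P07,1,0,1,0,1
P08,0,0,1,1,0
P09,0,0,0,0,1
P10,0,0,0,0,1
P11,0,0,0,0,1
P12,0,0,0,0,1
P13,0,0,0,0,1
P14,0,0,0,0,1
P15,0,0,0,0,1
P16,0,0,1,0,0
P17,0,0,0,0,0
P18,0,0,0,0,0
P19,0,0,0,0,0
P20,0,0,0,0,0
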