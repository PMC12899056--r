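SampleID,Ttotal,Tdisagreement,ADR_printed
9,3550,181,5.10
11,7488,92,1.23
13,15416,201,1.30
36,5082,82,1.61
50,9850,179,1.82
66,11350,332,2.93
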