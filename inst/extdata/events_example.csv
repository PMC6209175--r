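time_min,shelter_id,delta
5,S1,1
8,S1,1
12,S2,1
15,S1,-1
20,S1,1
31,S2,1
40,S1,1
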