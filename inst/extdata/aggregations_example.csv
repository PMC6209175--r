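site,aggregation_id,species,count
S1,A1,sp1,3
S1,A1,sp2,2
S1,A2,sp1,4
S1,A3,sp2,1
S2,A1,sp1,2
S2,A1,sp3,5
S2,A2,sp3,6
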