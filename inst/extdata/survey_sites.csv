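site,n_aggregations,n_individuals
site1,2,8
site2,16,182
site3,10,139
site4,7,34
site5,3,24
site6,12,244
site7,9,504
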