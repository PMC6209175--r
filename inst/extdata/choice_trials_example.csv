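experiment_id,trial_id,shelter1_label,shelter1_count,shelter2_label,shelter2_count,n_released
exp1,T1,occupied,14,empty,11,25
exp1,T2,occupied,16,empty,9,25
exp1,T3,occupied,13,empty,12,25
exp1,T4,occupied,18,empty,7,25
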