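label,t,n,r
original_study,9.90,255,0.83
lab_replication,7.89,170,0.87
unpublished_replication,7.03,201,0.92
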