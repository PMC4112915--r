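label,t,n,r
original_study,4.41,255,0.88
lab_replication,2.15,170,0.91
unpublished_replication,1.71,201,0.95
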