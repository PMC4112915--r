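question_id,truth
q1,6.3
q2,44.4
q3,30.3
q4,10.5
q5,58
q6,72.4
q7,18.9
q8,20.3
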