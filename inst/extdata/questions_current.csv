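question_id,truth
q1,6.3
q2,43.3
q3,32.3
q4,13.4
q5,53.6
q6,54.8
q7,26.4
q8,22.4
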