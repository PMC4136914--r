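disorder_id,subtype_id,weight
anxiety,gad,0.13639845
anxiety,other_anxiety,0.86360155
mood,unipolar,0.82079408
mood,bipolar,0.17920592
headache,migraine,0.33000858
headache,tension_type,0.53508972
headache,medication_overuse,0.1149017
headache,other_headache,0.02
neuromuscular,als,0.1
neuromuscular,other_nmd,0.9
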