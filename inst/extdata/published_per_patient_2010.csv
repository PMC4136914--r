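disorder_id,n_patients,cost_healthcare,cost_nonmedical,cost_indirect
addiction,1437560,1335,867,1315
anxiety,6238499,689,24,948
brain_tumor,20695,12428,0,6826
child_adolescent,480074,392,3021,0
dementia,608711,5830,19473,0
eating,131049,364,45,90
epilepsy,225346,4734,619,1827
headache,13909125,233,0,168
intellectual_disability,376777,6409,3203,0
mood,3002725,1514,469,1601
multiple_sclerosis,36193,12291,12495,12160
neuromuscular,23003,4605,3227,14185
parkinson,79789,8614,4866,9612
personality,396532,697,583,3979
psychotic,453650,5870,0,11705
sleep,4072265,396,0,284
somatoform,1852405,426,0,465
stroke,644025,3461,9032,835
tbi,335260,2412,830,4183
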