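disorder_id,n_patients,working_age_fraction
addiction,1437560,1
anxiety,6238499,1
brain_tumor,20695,1
child_adolescent,480074,1
dementia,608711,1
eating,131049,1
epilepsy,225346,1
headache,13909125,1
intellectual_disability,376777,1
mood,3002725,1
multiple_sclerosis,36193,1
neuromuscular,23003,1
parkinson,79789,1
personality,396532,1
psychotic,453650,1
sleep,4072265,1
somatoform,1852405,1
stroke,644025,1
tbi,335260,1
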