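disorder_id,group,indirect_forced_zero
addiction,mental,FALSE
anxiety,mental,FALSE
brain_tumor,neurological,FALSE
child_adolescent,mental,TRUE
dementia,neurological,TRUE
eating,mental,FALSE
epilepsy,neurological,FALSE
headache,neurological,FALSE
intellectual_disability,mental,FALSE
mood,mental,FALSE
multiple_sclerosis,neurological,FALSE
neuromuscular,neurological,FALSE
parkinson,neurological,FALSE
personality,mental,FALSE
psychotic,mental,FALSE
sleep,mental,FALSE
somatoform,mental,FALSE
stroke,neurological,FALSE
tbi,neurological,FALSE
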