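disorder_id,subtype_id,category,amount_eur2010,source
addiction,NA,healthcare,1335,printed
addiction,NA,nonmedical,867,printed
addiction,NA,indirect,1315,printed
brain_tumor,NA,healthcare,12428,printed
brain_tumor,NA,indirect,6826,printed
child_adolescent,NA,healthcare,392,printed
child_adolescent,NA,nonmedical,3021,printed
eating,NA,healthcare,364,printed
eating,NA,nonmedical,45,printed
eating,NA,indirect,90,printed
intellectual_disability,NA,healthcare,6409,printed
intellectual_disability,NA,nonmedical,3203,printed
personality,NA,healthcare,697,printed
personality,NA,nonmedical,583,printed
personality,NA,indirect,3979,printed
sleep,NA,healthcare,396,printed
sleep,NA,indirect,284,printed
somatoform,NA,healthcare,426,printed
somatoform,NA,indirect,465,printed
tbi,NA,healthcare,2412,printed
tbi,NA,nonmedical,830,printed
tbi,NA,indirect,4183,printed
psychotic,NA,indirect,11705,printed
anxiety,other_anxiety,healthcare,590.9361,reconstructed
anxiety,other_anxiety,indirect,334.1733,reconstructed
mood,unipolar,nonmedical,469,printed
mood,bipolar,nonmedical,469,printed
mood,bipolar,indirect,3165.8927,reconstructed
neuromuscular,other_nmd,healthcare,4081.1163,reconstructed
neuromuscular,other_nmd,nonmedical,1053.8946,reconstructed
neuromuscular,other_nmd,indirect,14653.6225,reconstructed
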