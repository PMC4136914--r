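study_id,disorder_id,subtype_id,costing_year,currency,cost_healthcare,cost_nonmedical,cost_indirect,basis,indirect_basis,quality_high,excluded_outlier
Rovira 2012,anxiety,gad,2006,EUR,1206,162,4451,prevalence,working_age,FALSE,FALSE
Coduras 2010,dementia,alzheimer,2006,EUR,4272,12708,NA,prevalence,working_age,TRUE,FALSE
Lopez-Bastida 2006,dementia,alzheimer,2001,EUR,3289,24281,628,prevalence,working_age,TRUE,FALSE
Lopez-Pousa 2004,dementia,alzheimer,2001,EUR,NA,NA,6649,prevalence,working_age,FALSE,FALSE
Sicras 2005,dementia,alzheimer,2003,EUR,5706,15444,NA,prevalence,working_age,FALSE,FALSE
Turro-Garriga 2010,dementia,alzheimer,2006,EUR,8212,NA,NA,prevalence,working_age,FALSE,FALSE
Gustavsson 2011,dementia,alzheimer,2007,GBP,4189,18504,NA,prevalence,working_age,FALSE,FALSE
Sicras 2005,dementia,vascular,2003,EUR,6090,20034,NA,prevalence,working_age,FALSE,FALSE
Oliva 2007,dementia,alzheimer,2002,EUR,NA,11110,NA,prevalence,working_age,TRUE,FALSE
Wimo 2007,dementia,alzheimer,2005,USD,6219,14989,NA,prevalence,working_age,FALSE,FALSE
Sancho 2008,epilepsy,NA,2005,EUR,4982,255,1618,prevalence,working_age,TRUE,FALSE
Villanueva 2012,epilepsy,NA,2010,EUR,3843,951,NA,prevalence,working_age,TRUE,FALSE
Badia 2004,headache,migraine,2001,EUR,198,NA,54,prevalence,working_age,TRUE,FALSE
Bloudek 2012,headache,migraine,2010,EUR,1217,NA,NA,prevalence,working_age,FALSE,FALSE
Linde 2012,headache,migraine,2010,EUR,130,NA,257,prevalence,working_age,TRUE,FALSE
Linde 2012,headache,tension_type,2010,EUR,19,NA,26,prevalence,working_age,TRUE,FALSE
Linde 2012,headache,medication_overuse,2010,EUR,404,NA,873,prevalence,working_age,TRUE,FALSE
Linde 2012,headache,other_headache,2010,EUR,22,NA,0,prevalence,working_age,TRUE,FALSE
Salvador-Carulla 2011,mood,unipolar,2006,EUR,4002,NA,1346,prevalence,working_age,TRUE,FALSE
Sicras-Mainar 2012,mood,unipolar,2009,EUR,620,NA,1275,prevalence,working_age,FALSE,FALSE
Sicras-Mainar 2010,mood,unipolar,2006,EUR,1579,NA,1810,prevalence,working_age,FALSE,FALSE
Serna 2007,mood,unipolar,2004,EUR,335,NA,268,prevalence,working_age,FALSE,FALSE
Gonzalez-Pinto 2010,mood,bipolar,2003,EUR,283,NA,NA,prevalence,working_age,FALSE,FALSE
Kobelt 2006,multiple_sclerosis,NA,2005,EUR,12142,12540,8145,prevalence,working_age,TRUE,FALSE
Arroyo 2011,multiple_sclerosis,NA,2009,EUR,9895,5510,NA,prevalence,working_age,FALSE,FALSE
Casado 2006,multiple_sclerosis,NA,2004,EUR,7775,21297,16618,prevalence,working_age,TRUE,FALSE
Karampampa 2012,multiple_sclerosis,NA,2009,EUR,15958,5235,7732,prevalence,working_age,TRUE,FALSE
Cubo 2009,parkinson,NA,2004,EUR,7380,3817,8235,prevalence,working_age,FALSE,FALSE
Oliva 2007,parkinson,NA,2002,EUR,NA,4255,NA,prevalence,working_age,TRUE,FALSE
Olivares 2008,psychotic,NA,2005,EUR,5569,NA,NA,prevalence,working_age,FALSE,FALSE
Vazquez-Polo 2005,psychotic,NA,1999,EUR,3989,NA,NA,prevalence,working_age,FALSE,FALSE
Beguiristain 2005,stroke,NA,2002,EUR,5048,NA,NA,prevalence,working_age,TRUE,FALSE
Hervas-Angulo 2006,stroke,NA,2004,EUR,2271,1863,426,prevalence,working_age,TRUE,FALSE
Mar 2011,stroke,NA,2008,EUR,16341,10932,NA,prevalence,working_age,FALSE,TRUE
Sicras 2008,stroke,NA,2006,EUR,1591,NA,NA,prevalence,working_age,FALSE,FALSE
Oliva 2007,stroke,NA,2002,EUR,NA,4478,NA,prevalence,working_age,TRUE,FALSE
Hervas 2007,stroke,NA,2004,EUR,NA,21551,NA,prevalence,working_age,FALSE,TRUE
Navarrete-Navarro 2007,stroke,NA,2004,EUR,1425,5537,741,prevalence,working_age,TRUE,FALSE
Hervas-Angulo 2006,stroke,NA,2004,EUR,4470,1289,572,incidence,working_age,TRUE,FALSE
Navarrete-Navarro 2007,stroke,NA,2004,EUR,5173,6420,2347,incidence,working_age,TRUE,FALSE
Lopez-Bastida 2009,neuromuscular,als,2004,EUR,8018,19602,8575,prevalence,working_age,TRUE,FALSE
Mar 2011,tbi,NA,2008,EUR,11109,8914,NA,prevalence,working_age,FALSE,TRUE
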