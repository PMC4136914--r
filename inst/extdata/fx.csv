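currency,year,eur_per_unit
USD,2004,0.803923
USD,2005,0.803794
USD,2006,0.796432
USD,2007,0.729661
USD,2008,0.679902
USD,2009,0.716949
USD,2010,0.754318
GBP,2004,1.473492
GBP,2005,1.462416
GBP,2006,1.466856
GBP,2007,1.461262
GBP,2008,1.25584
GBP,2009,1.12241
GBP,2010,1.165719
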