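year,index
1995,66.462075
1996,68.85471
1997,70.231804
1998,71.495977
1999,73.140384
2000,75.627157
2001,78.349735
2002,81.091976
2003,83.524735
2004,86.030477
2005,88.955513
2006,92.068956
2007,94.646887
2008,98.527409
2009,98.231827
2010,100
2011,103.2
2012,105.6768
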