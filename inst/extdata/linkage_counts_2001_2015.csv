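year,submitted,linked
2001,2448609,961605
2002,2319071,1175223
2003,2224872,1179781
2004,2165661,1144809
2005,2161484,1183292
2006,2050534,1271179
2007,1961446,1087254
2008,1936675,1077781
2009,1855919,1052394
2010,1778515,1067417
2011,1765211,1249492
2012,1662414,1251251
2013,1505476,1227162
2014,1271156,1043499
2015,592848,475275
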