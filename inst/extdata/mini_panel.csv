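county_id,year,category,population,beds,doctors,nurses,health_practitioners,income,gdp_per_capita,altitude
NMC_001,2009,NMC,259167,848,401,240,844,40993.37917513857,23144.588284875055,898.090836155463
NMC_001,2010,NMC,260463,923,422,269,909,44272.84950914966,25227.601230513814,898.090836155463
Yi_001,2009,Yi,225162,433,117,151,343,38047.79739954762,8576.101810244678,2571.1660318423314
Yi_001,2010,Yi,226288,475,117,171,368,41091.62119151143,9347.9509731667,2571.1660318423314
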