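quantity,indicator,category,year,value,rounding
aggregate_growth_pct,Bed_p1000,Yi,NA,140,int
aggregate_growth_pct,Bed_p1000,OMC,NA,127,int
aggregate_growth_pct,Bed_p1000,NMC,NA,121,int
aggregate_growth_pct,Doc_p1000,Yi,NA,20,int
aggregate_growth_pct,Doc_p1000,Zang,NA,11,int
aggregate_growth_pct,Doc_p1000,NMC,NA,61,int
aggregate_growth_pct,Nur_p1000,Yi,NA,240,int
aggregate_growth_pct,Nur_p1000,OMC,NA,316,int
aggregate_growth_pct,Nur_p1000,NMC,NA,198,int
share_negative_pct,Doc_p1000,Yi,NA,33,int
share_negative_pct,Doc_p1000,Zang,NA,50,int
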