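county_id,category
NMC_001,NMC
NMC_002,NMC
NMC_003,NMC
NMC_004,NMC
NMC_005,NMC
NMC_006,NMC
NMC_007,NMC
NMC_008,NMC
NMC_009,NMC
NMC_010,NMC
NMC_011,NMC
NMC_012,NMC
NMC_013,NMC
NMC_014,NMC
NMC_015,NMC
NMC_016,NMC
NMC_017,NMC
NMC_018,NMC
NMC_019,NMC
NMC_020,NMC
NMC_021,NMC
NMC_022,NMC
NMC_023,NMC
NMC_024,NMC
NMC_025,NMC
NMC_026,NMC
NMC_027,NMC
NMC_028,NMC
NMC_029,NMC
NMC_030,NMC
NMC_031,NMC
NMC_032,NMC
NMC_033,NMC
NMC_034,NMC
NMC_035,NMC
NMC_036,NMC
NMC_037,NMC
NMC_038,NMC
NMC_039,NMC
NMC_040,NMC
NMC_041,NMC
NMC_042,NMC
NMC_043,NMC
NMC_044,NMC
NMC_045,NMC
NMC_046,NMC
NMC_047,NMC
NMC_048,NMC
NMC_049,NMC
NMC_050,NMC
NMC_051,NMC
NMC_052,NMC
NMC_053,NMC
NMC_054,NMC
NMC_055,NMC
NMC_056,NMC
NMC_057,NMC
NMC_058,NMC
NMC_059,NMC
NMC_060,NMC
NMC_061,NMC
NMC_062,NMC
NMC_063,NMC
NMC_064,NMC
NMC_065,NMC
NMC_066,NMC
NMC_067,NMC
NMC_068,NMC
NMC_069,NMC
NMC_070,NMC
NMC_071,NMC
NMC_072,NMC
NMC_073,NMC
NMC_074,NMC
NMC_075,NMC
NMC_076,NMC
NMC_077,NMC
NMC_078,NMC
NMC_079,NMC
NMC_080,NMC
NMC_081,NMC
NMC_082,NMC
OMC_001,OMC
OMC_002,OMC
OMC_003,OMC
OMC_004,OMC
OMC_005,OMC
OMC_006,OMC
OMC_007,OMC
OMC_008,OMC
OMC_009,OMC
OMC_010,OMC
OMC_011,OMC
OMC_012,OMC
OMC_013,OMC
OMC_014,OMC
OMC_015,OMC
OMC_016,OMC
OMC_017,OMC
OMC_018,OMC
OMC_019,OMC
OMC_020,OMC
OMC_021,OMC
OMC_022,OMC
OMC_023,OMC
PSC_001,PSC
PSC_002,PSC
PSC_003,PSC
PSC_004,PSC
PSC_005,PSC
PSC_006,PSC
PSC_007,PSC
PSC_008,PSC
PSC_009,PSC
PSC_010,PSC
PSC_011,PSC
PSC_012,PSC
PSC_013,PSC
PSC_014,PSC
PSC_015,PSC
PSC_016,PSC
PSC_017,PSC
PSC_018,PSC
PSC_019,PSC
PSC_020,PSC
PSC_021,PSC
PSC_022,PSC
PSC_023,PSC
PSC_024,PSC
PSC_025,PSC
PSC_026,PSC
PSC_027,PSC
PSC_028,PSC
PSC_029,PSC
PSC_030,PSC
PSC_031,PSC
PSC_032,PSC
Yi_001,Yi
Yi_002,Yi
Yi_003,Yi
Yi_004,Yi
Yi_005,Yi
Yi_006,Yi
Yi_007,Yi
Yi_008,Yi
Yi_009,Yi
Yi_010,Yi
Yi_011,Yi
Yi_012,Yi
Zang_001,Zang
Zang_002,Zang
Zang_003,Zang
Zang_004,Zang
Zang_005,Zang
Zang_006,Zang
Zang_007,Zang
Zang_008,Zang
Zang_009,Zang
Zang_010,Zang
Zang_011,Zang
Zang_012,Zang
Zang_013,Zang
Zang_014,Zang
Zang_015,Zang
Zang_016,Zang
Zang_017,Zang
Zang_018,Zang
Zang_019,Zang
Zang_020,Zang
Zang_021,Zang
Zang_022,Zang
Zang_023,Zang
Zang_024,Zang
Zang_025,Zang
Zang_026,Zang
Zang_027,Zang
Zang_028,Zang
Zang_029,Zang
Zang_030,Zang
Zang_031,Zang
Zang_032,Zang
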