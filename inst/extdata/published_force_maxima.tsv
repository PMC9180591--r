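peptide	velocity	com	atom
P1	0.1	7328	2595
P1	0.05	6049	2388
P1	0.01	4561	2035
P2	0.1	7329	3119
P2	0.05	6123	2613
P2	0.01	3955	2017
P3	0.1	3689	1813
P3	0.05	3325	1602
P3	0.01	2414	1338
P4	0.1	3209	1869
P4	0.05	2944	1642
P4	0.01	2532	1541
P5	0.1	4476	2785
P5	0.05	3983	2886
P5	0.01	2800	2704
P6	0.1	4277	1897
P6	0.05	3357	1837
P6	0.01	2533	1454
P7	0.1	3559	1870
P7	0.05	3086	1748
P7	0.01	2454	1518
CPP	0.1	5107	2785
CPP	0.05	4934	2886
CPP	0.01	3828	2704
PolyAla	0.1	1201	1201
PolyAla	0.05	1258	1226
PolyAla	0.01	NA	NA
PolyLeu	0.1	4347	2048
PolyLeu	0.05	1735	1936
PolyLeu	0.01	NA	NA
PolyMet	0.1	4405	1819
PolyMet	0.05	3880	1529
PolyMet	0.01	NA	NA
PolyArg	0.1	5402	3124
PolyArg	0.05	5040	2779
PolyArg	0.01	NA	NA
PolyGlu	0.1	6621	2557
PolyGlu	0.05	5594	2444
PolyGlu	0.01	NA	NA
LipidDirect	0.1	2218	NA
LipidDirect	0.05	NA	NA
LipidDirect	0.01	NA	NA
LipidReverse	0.1	2655	NA
LipidReverse	0.05	NA	NA
LipidReverse	0.01	NA	NA
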