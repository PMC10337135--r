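# Published attributable cases and deaths of non-communicable diseases by
# scenario over the 2019-2030 simulation (Chilean adults aged 20-80),
# with 95% CIs as printed. total_cancer rows are the printed subtotals.
# Repairs forced by the column-sum identities:
#   cases/cirrhosis/BAU: printed "1,.630" stored as 14630, the unique value
#     making the BAU cases column sum to the printed total 669100 (and
#     consistent with the neighbouring 14439/14359/14046).
#   cases/stroke/S2: printed "78,.493" stored as 78493, forced by the
#     printed Scenario-2 total 659010.
# Unparseable CI cells stored as NA:
#   cases/ckd/BAU ci_low printed "159,46"; deaths/stroke/S3 ci_low
#   printed "23.,91".
outcome,disease_id,scenario_id,value,ci_low,ci_high
cases,chd,BAU,53463,49543,57741
cases,stroke,BAU,79859,68969,92564
cases,hhd,BAU,9091,7837,10569
cases,t2dm,BAU,302103,264342,344064
cases,ckd,BAU,199638,NA,249870
cases,cirrhosis,BAU,14630,12587,17001
cases,colorectal_cancer,BAU,4819,4657,4980
cases,kidney_cancer,BAU,1060,985,1140
cases,liver_cancer,BAU,1466,1256,1705
cases,breast_cancer,BAU,1860,1790,1926
cases,pancreatic_cancer,BAU,1111,1081,1152
cases,total_cancer,BAU,10316,9770,10903
cases,chd,S1,52729,48862,56947
cases,stroke,S1,78889,68131,91439
cases,hhd,S1,9008,7766,10473
cases,t2dm,S1,299371,261952,340953
cases,ckd,S1,197349,157636,247005
cases,cirrhosis,S1,14439,12422,16778
cases,colorectal_cancer,S1,4757,4597,4916
cases,kidney_cancer,S1,1047,974,1126
cases,liver_cancer,S1,1450,1243,1687
cases,breast_cancer,S1,1839,1773,1905
cases,pancreatic_cancer,S1,1097,1067,1137
cases,total_cancer,S1,10190,9654,10771
cases,chd,S2,52432,48587,56626
cases,stroke,S2,78493,67789,90981
cases,hhd,S2,8974,7736,10433
cases,t2dm,S2,298243,260965,339669
cases,ckd,S2,196416,158910,245837
cases,cirrhosis,S2,14359,12350,16685
cases,colorectal_cancer,S2,4709,4551,4866
cases,kidney_cancer,S2,1038,965,1116
cases,liver_cancer,S2,1438,1233,1673
cases,breast_cancer,S2,1822,1757,1887
cases,pancreatic_cancer,S2,1086,1057,1126
cases,total_cancer,S2,10093,9563,10668
cases,chd,S3,50877,47146,54947
cases,stroke,S3,76499,66067,88670
cases,hhd,S3,8796,7583,10226
cases,t2dm,S3,292819,256219,333491
cases,ckd,S3,191547,153002,239743
cases,cirrhosis,S3,14046,12085,16322
cases,colorectal_cancer,S3,4444,4295,4593
cases,kidney_cancer,S3,984,915,1058
cases,liver_cancer,S3,1370,1174,1593
cases,breast_cancer,S3,1731,1669,1793
cases,pancreatic_cancer,S3,1022,994,1059
cases,total_cancer,S3,9551,9047,10096
deaths,chd,BAU,32303,29934,34887
deaths,stroke,BAU,28896,24956,33493
deaths,hhd,BAU,7494,6461,8713
deaths,t2dm,BAU,21796,19071,24823
deaths,ckd,BAU,9606,7673,12023
deaths,cirrhosis,BAU,10514,9046,12218
deaths,colorectal_cancer,BAU,3122,3017,3226
deaths,kidney_cancer,BAU,805,748,866
deaths,liver_cancer,BAU,1343,1151,1562
deaths,breast_cancer,BAU,464,447,480
deaths,pancreatic_cancer,BAU,1005,978,1042
deaths,total_cancer,BAU,6739,6341,7176
deaths,chd,S1,31860,29523,34408
deaths,stroke,S1,28528,24638,33067
deaths,hhd,S1,7424,6400,8631
deaths,t2dm,S1,21580,18883,24577
deaths,ckd,S1,9476,7569,11860
deaths,cirrhosis,S1,10373,8924,12054
deaths,colorectal_cancer,S1,3081,2978,3184
deaths,kidney_cancer,S1,795,739,855
deaths,liver_cancer,S1,1329,1139,1546
deaths,breast_cancer,S1,458,442,475
deaths,pancreatic_cancer,S1,993,966,1029
deaths,total_cancer,S1,6656,6264,7089
deaths,chd,S2,31681,29358,34216
deaths,stroke,S2,28379,24509,32894
deaths,hhd,S2,7396,6376,8598
deaths,t2dm,S2,21492,18806,24478
deaths,ckd,S2,9424,7527,11795
deaths,cirrhosis,S2,10314,8873,11985
deaths,colorectal_cancer,S2,3050,2948,3152
deaths,kidney_cancer,S2,788,732,847
deaths,liver_cancer,S2,1318,1129,1533
deaths,breast_cancer,S2,454,438,470
deaths,pancreatic_cancer,S2,983,956,1019
deaths,total_cancer,S2,6593,6203,7021
deaths,chd,S3,30777,28520,33239
deaths,stroke,S3,27663,NA,32064
deaths,hhd,S3,7249,6249,8427
deaths,t2dm,S3,21082,18447,24011
deaths,ckd,S3,9174,7328,11482
deaths,cirrhosis,S3,10086,8677,11720
deaths,colorectal_cancer,S3,2883,2786,2979
deaths,kidney_cancer,S3,748,695,804
deaths,liver_cancer,S3,1255,1076,1460
deaths,breast_cancer,S3,431,416,447
deaths,pancreatic_cancer,S3,927,801,960
deaths,total_cancer,S3,6244,5953,6650
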