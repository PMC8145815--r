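outcome,variable,category,no,yes,printed_chi2
outpatient,sex,Male,9712,1844,76.51
outpatient,sex,Female,10515,2672,76.51
outpatient,age_group,45-50,3560,739,4.17
outpatient,age_group,51-60,6986,1566,4.17
outpatient,age_group,61-70,6107,1391,4.17
outpatient,age_group,71+,3583,821,4.17
outpatient,education,Illiterate,6110,1475,22.65
outpatient,education,Elementary,9130,2066,22.65
outpatient,education,MiddleUp,4988,972,22.65
outpatient,economic_status,Low,4985,1153,3.62
outpatient,economic_status,Middle,10009,2239,3.62
outpatient,economic_status,High,5039,1067,3.62
outpatient,living_status,WithOthers,16031,3536,1.96
outpatient,living_status,Alone,4205,981,1.96
outpatient,sleeping_hours,7-8h,7532,1390,85.96
outpatient,sleeping_hours,<=6h,9930,2553,85.96
outpatient,sleeping_hours,>8h,2774,574,85.96
outpatient,smoking,No,11655,2853,7.95
outpatient,smoking,Yes,4375,953,7.95
outpatient,alcohol,No,13428,3304,77.48
outpatient,alcohol,Yes,6800,1212,77.48
outpatient,disability,No,14263,3003,44.50
outpatient,disability,Yes,3169,888,44.50
outpatient,body_pain,No,11077,1660,478.40
outpatient,body_pain,Yes,9159,2857,478.40
outpatient,chronic_diseases,No,9791,1305,567.35
outpatient,chronic_diseases,Yes,10445,3212,567.35
inpatient,sex,Male,10157,1444,2.12
inpatient,sex,Female,11491,1727,2.12
inpatient,age_group,45-50,4005,317,431.92
inpatient,age_group,51-60,7736,848,431.92
inpatient,age_group,61-70,6400,1109,431.92
inpatient,age_group,71+,3517,897,431.92
inpatient,education,Illiterate,6517,1084,59.33
inpatient,education,Elementary,9745,1486,59.33
inpatient,education,MiddleUp,5388,597,59.33
inpatient,economic_status,Low,5021,1124,270.04
inpatient,economic_status,Middle,10786,1500,270.04
inpatient,economic_status,High,5611,523,270.04
inpatient,living_status,WithOthers,17146,2450,6.03
inpatient,living_status,Alone,4512,721,6.03
inpatient,sleeping_hours,7-8h,7963,968,54.08
inpatient,sleeping_hours,<=6h,10716,1778,54.08
inpatient,sleeping_hours,>8h,2979,425,54.08
inpatient,smoking,No,12682,1864,58.16
inpatient,smoking,Yes,4888,477,58.16
inpatient,alcohol,No,14353,2428,133.00
inpatient,alcohol,Yes,7293,743,133.00
inpatient,disability,No,15613,1712,214.39
inpatient,disability,Yes,3341,733,214.39
inpatient,body_pain,No,11666,1123,376.96
inpatient,body_pain,Yes,9992,2048,376.96
inpatient,chronic_diseases,No,10177,944,331.67
inpatient,chronic_diseases,Yes,11481,2227,331.67
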