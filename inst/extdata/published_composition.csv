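variable,category,count,printed_pct
policy,Before,12145,48.87
policy,After,12705,51.13
sex,Male,11612,46.75
sex,Female,13228,53.25
age_group,45-50,4329,17.42
age_group,51-60,8594,34.58
age_group,61-70,7510,30.22
age_group,71+,4417,17.77
education,Illiterate,7606,30.62
education,Elementary,11238,45.25
education,MiddleUp,5992,24.13
economic_status,Low,6147,25.01
economic_status,Middle,12289,50.01
economic_status,High,6139,24.98
living_status,WithOthers,19607,78.90
living_status,Alone,5242,21.10
sleeping_hours,7-8h,8932,35.94
sleeping_hours,<=6h,12499,50.30
sleeping_hours,>8h,3419,13.76
smoking,No,14555,73.04
smoking,Yes,5373,26.96
alcohol,No,16791,67.62
alcohol,Yes,8042,32.38
disability,No,17341,80.97
disability,Yes,4075,19.03
body_pain,No,12807,51.54
body_pain,Yes,12043,48.46
chronic_diseases,No,11134,44.80
chronic_diseases,Yes,13716,55.20
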