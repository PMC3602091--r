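term_type,key,level,employment,ssi,income,missed_days
intercept,intercept,NA,NA,NA,4231,NA
sex,male,NA,1.75,0.86,2175,0.73
age,40-44,NA,1.51,1.47,7198,1.12
age,45-49,NA,1.54,1.71,7869,1.10
age,50-54,NA,1.39,1.95,7889,1.10
age,55-59,NA,0.95,2.15,7336,1.18
age,60-64,NA,0.45,2.08,5851,1.11
age,65-69,NA,0.16,1.58,3709,1.06
age,70+,NA,0.05,0.77,-1810,0.84
index,pf_index,NA,1.02,0.98,180,0.97
item,sit,2,0.94,1.06,87,1.10
item,sit,3,0.81,1.32,189,1.14
item,sit,4,0.72,1.57,1278,1.23
item,sit,5,0.50,1.35,-1323,1.19
item,reach,2,0.84,1.09,-361,1.08
item,reach,3,0.69,1.21,37,1.19
item,reach,4,0.53,1.55,-1093,1.11
item,reach,5,0.46,1.18,NA,2.01
item,stand,2,0.75,1.47,-116,1.06
item,stand,3,0.64,1.65,-870,1.40
item,stand,4,0.47,2.27,-574,1.23
item,stand,5,0.29,2.05,-337,1.28
cause,back,NA,1.09,1.02,-2116,1.50
cause,injury,NA,1.14,0.94,-1185,2.19
cause,msk,NA,0.86,1.21,-834,1.69
cause,arthritis,NA,1.20,1.15,-1893,1.28
year,2004,NA,1.24,0.86,2302,1.04
year,2005,NA,1.22,0.87,2362,1.12
year,2006,NA,1.20,0.85,2280,1.07
year,2007,NA,1.18,0.95,-2616,1.09
year,2008,NA,1.13,0.97,2169,1.04
year,2009,NA,1.04,0.93,557,1.02
education,hs,NA,1.45,0.42,18262,1.11
education,baccalaureate,NA,1.93,0.24,37808,1.02
education,post_baccalaureate,NA,1.96,0.19,49722,0.97
occupation,management,NA,NA,NA,9017,1.22
occupation,finance,NA,NA,NA,7635,1.36
occupation,computer,NA,NA,NA,8535,1.56
occupation,architect,NA,NA,NA,9342,1.49
occupation,social_sciences,NA,NA,NA,1828,1.38
occupation,social_services,NA,NA,NA,-4099,1.74
occupation,legal,NA,NA,NA,7877,1.54
occupation,education,NA,NA,NA,-1591,1.21
occupation,arts,NA,NA,NA,318,1.28
occupation,health_practitioner,NA,NA,NA,7404,1.35
occupation,healthcare_support,NA,NA,NA,-3600,1.50
occupation,protective_services,NA,NA,NA,5142,1.99
occupation,food_preparation,NA,NA,NA,-6835,1.26
occupation,cleaning,NA,NA,NA,-5245,1.39
occupation,personal_care,NA,NA,NA,-4045,1.16
occupation,sales,NA,NA,NA,2178,1.30
occupation,administrative_support,NA,NA,NA,2420,1.52
occupation,farm,NA,NA,NA,-2843,1.34
occupation,construction,NA,NA,NA,342,1.66
occupation,maintenance,NA,NA,NA,4799,1.82
occupation,production,NA,NA,NA,638,1.67
occupation,transport,NA,NA,NA,-287,1.80
occupation,military,NA,NA,NA,11409,0.93
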