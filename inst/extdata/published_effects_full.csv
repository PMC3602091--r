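term_type,key,level,employment,ssi,income,missed_days
intercept,intercept,NA,NA,NA,22242,NA
sex,male,NA,1.73,0.89,2141,0.74
age,40-44,NA,1.51,1.46,7192,1.12
age,45-49,NA,1.55,1.70,7887,1.10
age,50-54,NA,1.40,1.93,7917,1.10
age,55-59,NA,0.95,2.13,7383,1.17
age,60-64,NA,0.45,2.06,5940,1.11
age,65-69,NA,0.16,1.59,3908,1.07
age,70+,NA,0.05,0.76,-1804,0.84
item,walk,2,0.84,1.36,-1790,1.26
item,walk,3,0.77,1.49,-3434,1.40
item,walk,4,0.68,1.15,-3852,1.51
item,walk,5,0.57,1.19,-4347,1.54
item,climb,2,1.01,1.51,-2844,1.08
item,climb,3,0.94,1.78,-3102,1.10
item,climb,4,0.98,2.08,-2551,1.26
item,climb,5,0.78,2.23,-1663,1.35
item,sit,2,0.97,0.97,769,1.07
item,sit,3,0.81,1.24,450,1.14
item,sit,4,0.77,1.38,1846,1.16
item,sit,5,0.53,1.29,-1895,1.08
item,reach,2,0.91,0.92,201,1.07
item,reach,3,0.74,1.00,523,1.18
item,reach,4,0.61,1.23,-896,1.11
item,reach,5,0.55,1.09,NA,1.76
item,stand,2,0.78,1.24,974,1.01
item,stand,3,0.63,1.32,346,1.34
item,stand,4,0.48,1.65,1491,1.18
item,stand,5,0.31,1.78,-212,1.26
item,stoop,2,1.10,0.82,731,1.09
item,stoop,3,1.08,0.77,-347,1.19
item,stoop,4,1.10,0.79,-737,1.16
item,stoop,5,1.09,0.68,-357,1.42
item,lift,2,0.77,1.60,-1224,0.92
item,lift,3,0.79,1.61,-2497,0.94
item,lift,4,0.55,2.31,-5448,0.89
item,lift,5,0.64,2.15,-4122,1.26
item,push,2,0.89,1.04,-62,1.15
item,push,3,0.90,1.12,-1164,1.55
item,push,4,0.81,1.25,-933,1.43
item,push,5,0.56,1.18,935,2.08
cause,back,NA,1.09,1.01,-488,1.35
cause,injury,NA,1.09,0.95,604,2.02
cause,msk,NA,0.86,1.20,-835,1.69
cause,arthritis,NA,1.16,1.11,42,1.16
year,2004,NA,1.25,0.86,2305,1.04
year,2005,NA,1.22,0.87,2393,1.12
year,2006,NA,1.20,0.85,2328,1.07
year,2007,NA,1.18,0.95,-2583,1.09
year,2008,NA,1.13,0.98,2166,1.04
year,2009,NA,1.03,0.93,559,1.02
education,hs,NA,1.45,0.43,18214,1.11
education,baccalaureate,NA,1.93,0.24,37781,1.02
education,post_baccalaureate,NA,1.95,0.20,49648,0.97
occupation,management,NA,NA,NA,8981,1.22
occupation,finance,NA,NA,NA,7650,1.37
occupation,computer,NA,NA,NA,8524,1.57
occupation,architect,NA,NA,NA,9349,1.50
occupation,social_sciences,NA,NA,NA,1878,1.38
occupation,social_services,NA,NA,NA,-4019,1.74
occupation,legal,NA,NA,NA,7838,1.55
occupation,education,NA,NA,NA,-1624,1.21
occupation,arts,NA,NA,NA,318,1.28
occupation,health_practitioner,NA,NA,NA,7439,1.35
occupation,healthcare_support,NA,NA,NA,-3530,1.49
occupation,protective_services,NA,NA,NA,5146,2.00
occupation,food_preparation,NA,NA,NA,-6799,1.26
occupation,cleaning,NA,NA,NA,-5226,1.40
occupation,personal_care,NA,NA,NA,-3958,1.16
occupation,sales,NA,NA,NA,2187,1.31
occupation,administrative_support,NA,NA,NA,2442,1.52
occupation,farm,NA,NA,NA,-2767,1.33
occupation,construction,NA,NA,NA,330,1.66
occupation,maintenance,NA,NA,NA,4851,1.82
occupation,production,NA,NA,NA,679,1.68
occupation,transport,NA,NA,NA,-215,1.81
occupation,military,NA,NA,NA,11432,0.94
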