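"covariate","level","n_control","n_case","reference","or_published"
"AGE","<18",4011,143,TRUE,NA
"AGE","18-65",27788,4812,FALSE,4.86
"AGE","65-85",19174,4753,FALSE,6.95
"AGE",">85",2832,1409,FALSE,13.96
"WT","<50",11839,2542,TRUE,NA
"WT","50-100",38303,7169,FALSE,0.87
"WT",">100",2807,955,FALSE,1.58
"SEX","Female",32733,7315,TRUE,NA
"SEX","Male",21016,3799,FALSE,0.81
"TIME","<365",48825,9943,TRUE,NA
"TIME","365-730",2696,558,FALSE,1.02
"TIME",">730",2284,616,FALSE,1.32
"DRUG","Avatrombopag",218,127,TRUE,NA
"DRUG","Eltrombopag",24122,5924,FALSE,0.42
"DRUG","Romiplostim",29465,5066,FALSE,0.3
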