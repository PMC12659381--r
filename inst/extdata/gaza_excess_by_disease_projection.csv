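disease,scenario,sub_period,mean,pi_lo,pi_hi
ihd,ceasefire,proj_m1_3,776,685,867
ihd,ceasefire,proj_m4_6,651,569,739
ihd,ceasefire,total,1427,1254,1606
ihd,status_quo,proj_m1_3,992,893,1091
ihd,status_quo,proj_m4_6,962,863,1062
ihd,status_quo,total,1954,1757,2153
ihd,escalation,proj_m1_3,1044,942,1145
ihd,escalation,proj_m4_6,1006,902,1111
ihd,escalation,total,2050,1845,2256
ckd_dialysis,ceasefire,proj_m1_3,21,5,38
ckd_dialysis,ceasefire,proj_m4_6,15,2,33
ckd_dialysis,ceasefire,total,36,7,70
ckd_dialysis,status_quo,proj_m1_3,34,16,57
ckd_dialysis,status_quo,proj_m4_6,32,14,55
ckd_dialysis,status_quo,total,67,29,112
ckd_dialysis,escalation,proj_m1_3,39,20,63
ckd_dialysis,escalation,proj_m4_6,38,18,61
ckd_dialysis,escalation,total,77,37,124
dm1,ceasefire,proj_m1_3,18,0,53
dm1,ceasefire,proj_m4_6,18,0,51
dm1,ceasefire,total,36,0,104
dm1,status_quo,proj_m1_3,97,53,161
dm1,status_quo,proj_m4_6,95,48,153
dm1,status_quo,total,191,101,313
dm1,escalation,proj_m1_3,141,79,212
dm1,escalation,proj_m4_6,130,76,198
dm1,escalation,total,271,154,410
stroke,ceasefire,proj_m1_3,70,22,131
stroke,ceasefire,proj_m4_6,59,12,117
stroke,ceasefire,total,129,34,247
stroke,status_quo,proj_m1_3,92,37,155
stroke,status_quo,proj_m4_6,88,33,153
stroke,status_quo,total,180,71,308
stroke,escalation,proj_m1_3,99,40,164
stroke,escalation,proj_m4_6,91,37,162
stroke,escalation,total,191,77,326
cancer,ceasefire,proj_m1_3,30,6,71
cancer,ceasefire,proj_m4_6,23,-4,57
cancer,ceasefire,total,53,2,128
cancer,status_quo,proj_m1_3,46,12,88
cancer,status_quo,proj_m4_6,43,8,86
cancer,status_quo,total,89,20,174
cancer,escalation,proj_m1_3,45,12,90
cancer,escalation,proj_m4_6,42,7,84
cancer,escalation,total,87,19,173
total,ceasefire,proj_m1_3,915,718,1159
total,ceasefire,proj_m4_6,766,579,996
total,ceasefire,total,1680,1297,2155
total,status_quo,proj_m1_3,1261,1011,1552
total,status_quo,proj_m4_6,1219,966,1509
total,status_quo,total,2480,1977,3061
total,escalation,proj_m1_3,1368,1093,1674
total,escalation,proj_m4_6,1308,1039,1616
total,escalation,total,2676,2132,3290
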