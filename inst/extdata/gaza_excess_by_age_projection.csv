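stratum,scenario,sub_period,mean,pi_lo,pi_hi
0-9,ceasefire,proj_m1_3,1,0,3
0-9,ceasefire,proj_m4_6,1,0,3
0-9,ceasefire,total,2,0,7
0-9,status_quo,proj_m1_3,7,3,10
0-9,status_quo,proj_m4_6,7,2,10
0-9,status_quo,total,12,7,21
0-9,escalation,proj_m1_3,9,5,13
0-9,escalation,proj_m4_6,9,5,13
0-9,escalation,total,18,10,28
10-19,ceasefire,proj_m1_3,4,1,8
10-19,ceasefire,proj_m4_6,3,0,8
10-19,ceasefire,total,6,1,16
10-19,status_quo,proj_m1_3,14,8,23
10-19,status_quo,proj_m4_6,14,7,22
10-19,status_quo,total,26,15,44
10-19,escalation,proj_m1_3,19,11,29
10-19,escalation,proj_m4_6,18,11,28
10-19,escalation,total,38,22,75
20-29,ceasefire,proj_m1_3,8,4,15
20-29,ceasefire,proj_m4_6,7,3,14
20-29,ceasefire,total,15,6,29
20-29,status_quo,proj_m1_3,22,14,35
20-29,status_quo,proj_m4_6,22,13,33
20-29,status_quo,total,44,26,68
20-29,escalation,proj_m1_3,30,18,44
20-29,escalation,proj_m4_6,28,18,41
20-29,escalation,total,58,36,85
30-39,ceasefire,proj_m1_3,16,11,25
30-39,ceasefire,proj_m4_6,14,8,22
30-39,ceasefire,total,30,19,46
30-39,status_quo,proj_m1_3,31,21,44
30-39,status_quo,proj_m4_6,30,20,42
30-39,status_quo,total,61,41,86
30-39,escalation,proj_m1_3,38,25,52
30-39,escalation,proj_m4_6,35,24,49
30-39,escalation,total,73,50,100
40-49,ceasefire,proj_m1_3,51,37,71
40-49,ceasefire,proj_m4_6,43,30,61
40-49,ceasefire,total,94,67,132
40-49,status_quo,proj_m1_3,83,62,111
40-49,status_quo,proj_m4_6,81,59,107
40-49,status_quo,total,164,120,217
40-49,escalation,proj_m1_3,96,71,126
40-49,escalation,proj_m4_6,91,67,120
40-49,escalation,total,188,138,246
50-59,ceasefire,proj_m1_3,118,93,151
50-59,ceasefire,proj_m4_6,99,74,129
50-59,ceasefire,total,217,167,281
50-59,status_quo,proj_m1_3,166,132,205
50-59,status_quo,proj_m4_6,159,125,199
50-59,status_quo,total,325,257,404
50-59,escalation,proj_m1_3,180,143,222
50-59,escalation,proj_m4_6,172,135,213
50-59,escalation,total,352,278,435
60-69,ceasefire,proj_m1_3,176,140,220
60-69,ceasefire,proj_m4_6,146,112,188
60-69,ceasefire,total,322,252,408
60-69,status_quo,proj_m1_3,236,192,287
60-69,status_quo,proj_m4_6,227,183,278
60-69,status_quo,total,464,375,565
60-69,escalation,proj_m1_3,253,206,306
60-69,escalation,proj_m4_6,241,194,294
60-69,escalation,total,494,400,600
70-79,ceasefire,proj_m1_3,223,177,278
70-79,ceasefire,proj_m4_6,186,142,238
70-79,ceasefire,total,409,320,515
70-79,status_quo,proj_m1_3,293,239,353
70-79,status_quo,proj_m4_6,283,228,344
70-79,status_quo,total,576,467,697
70-79,escalation,proj_m1_3,311,254,374
70-79,escalation,proj_m4_6,297,241,361
70-79,escalation,total,609,495,735
80+,ceasefire,proj_m1_3,318,256,387
80+,ceasefire,proj_m4_6,267,209,334
80+,ceasefire,total,585,466,722
80+,status_quo,proj_m1_3,409,340,485
80+,status_quo,proj_m4_6,398,328,475
80+,status_quo,total,807,669,960
80+,escalation,proj_m1_3,431,359,509
80+,escalation,proj_m4_6,416,344,497
80+,escalation,total,847,703,1005
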