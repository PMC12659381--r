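disease,sub_period,mean,pi_lo,pi_hi
ihd,to_date,1242,1114,1376
ckd_dialysis,to_date,33,13,58
dm1,to_date,27,0,71
stroke,to_date,115,45,196
cancer,to_date,62,20,117
total,to_date,1479,1192,1818
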