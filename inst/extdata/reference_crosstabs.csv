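variable,level,score0,score1,score2,score3,risk_low,risk_high,ordinal
age_group,<=30,0,1,1,1,1,2,TRUE
age_group,31-40,2,4,1,3,6,4,TRUE
age_group,41-50,4,6,4,0,10,4,TRUE
age_group,51-60,4,6,0,3,10,3,TRUE
age_group,>60,9,3,5,1,12,6,TRUE
gender,male,15,15,10,8,30,18,FALSE
gender,female,4,5,1,0,9,1,FALSE
site,tongue_lateral,10,12,5,2,22,7,FALSE
site,alveolus_upper,0,1,1,0,1,1,FALSE
site,alveolus_lower,3,1,1,2,4,3,FALSE
site,retromolar,0,0,0,1,0,1,FALSE
site,buccal_mucosa,5,6,4,3,11,7,FALSE
site,hard_palate,1,0,0,0,1,0,FALSE
p_staging,stage1,1,0,0,1,1,1,TRUE
p_staging,stage2,5,4,1,0,9,1,TRUE
p_staging,stage3,7,7,3,1,14,4,TRUE
p_staging,stage4,6,9,7,6,15,13,TRUE
p_n,N0,9,9,2,1,18,3,TRUE
p_n,N1,7,6,4,2,13,6,TRUE
p_n,N2,1,4,1,2,5,3,TRUE
p_n,N3,2,1,4,3,3,7,TRUE
c_staging,stage1,1,0,0,0,1,0,TRUE
c_staging,stage2,7,3,0,0,10,0,TRUE
c_staging,stage3,8,10,5,6,18,11,TRUE
c_staging,stage4,3,7,6,2,10,8,TRUE
c_n,N0,12,9,2,3,21,5,TRUE
c_n,N1,5,9,4,4,14,8,TRUE
c_n,N2,1,2,3,1,3,4,TRUE
c_n,N3,1,0,2,0,1,2,TRUE
grading,well,9,3,1,0,12,1,TRUE
grading,moderate,8,12,8,8,20,16,TRUE
grading,poor,2,5,2,0,7,2,TRUE
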