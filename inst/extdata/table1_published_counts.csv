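variable,category,is_reference,n_died,n_discharged
overall,all,0,152,2030
age_band,band_2_5,1,80,783
age_band,band_6_12,0,44,722
age_band,band_13_24,0,28,525
sex,female,1,78,856
sex,male,0,74,1174
resp_rate_cat,below_cutoff,1,46,713
resp_rate_cat,above_0_9,0,35,583
resp_rate_cat,above_10_19,0,30,435
resp_rate_cat,above_20_plus,0,41,299
muac_cat,normal,1,37,1279
muac_cat,moderate,0,29,372
muac_cat,severe,0,86,379
waz_cat,normal,1,63,1347
waz_cat,moderate,0,35,383
waz_cat,severe,0,54,300
wlz_cat,normal,1,101,1662
wlz_cat,moderate,0,36,264
wlz_cat,severe,0,15,104
conscious_level,normal,1,58,1525
conscious_level,agitated,0,14,53
conscious_level,lethargic,0,30,305
conscious_level,prostrate,0,36,127
conscious_level,unconscious,0,14,20
spo2_cat,gt92,1,78,1700
spo2_cat,s90_92,0,8,112
spo2_cat,lt90,0,66,218
chest_indrawing,present,0,143,2001
convulsion,present,0,13,77
cough,present,0,129,1925
crackles,present,0,71,1062
cyanosis,present,0,12,17
decreased_skin_turgor,present,0,13,24
deep_breathing,present,0,70,410
diarrhea,present,0,27,282
head_nodding,present,0,28,347
nasal_flaring,present,0,105,1327
pallor,present,0,59,328
sunken_eye,present,0,18,66
vomiting,present,0,36,398
vomits_everything,present,0,17,110
unable_to_drink,present,0,42,202
wheeze,present,0,19,353
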