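woman_id,registry_id,diagnosis_date,group,first_notification_date
w1,R1,2004-03-15,breast,2004-03-15
w2,R2,2003-08-01,melanoma,2003-08-01
w3,R3,2005-12-01,thyroid_endocrine,2005-12-01
w4,R4,1998-06-10,lymphohaematopoeitic,1998-06-10
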