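woman_id,maternity_id,delivery_date,gestation_weeks
w1,m1,2004-06-30,40
w2,m2,2003-05-10,38
w3,m3,2005-09-15,41
w4,m4,2002-11-20,37
w5,m5,2006-03-08,40
w6,m6,2007-08-25,39
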