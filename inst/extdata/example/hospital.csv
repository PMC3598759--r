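woman_id,record_id,admission_date,diag1,diag2,diag3
w1,1,2004-03-10,C50.9,,
w1,2,2004-04-02,Z51.1,C50.1,
w2,3,2003-08-01,O26.8,C43.2,
w4,4,2003-02-10,C81.1,,
w5,5,2006-01-15,O80,Z37.0,
w9,6,2006-05-05,C50.9,,
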