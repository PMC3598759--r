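study_start: '2001-01-01'
study_end: '2008-12-31'
maternities_per_woman:
  '1': 0.62
  '2': 0.32
  '3': 0.055
  '4': 0.005
interpregnancy_gap_days:
- 400
- 1100
gestation_weeks:
  '20': 0.00040192926045
  '21': 0.00040192926045
  '22': 0.00040192926045
  '23': 0.00040192926045
  '24': 0.00040192926045
  '25': 0.00040192926045
  '26': 0.00040192926045
  '27': 0.00040192926045
  '28': 0.001507234726688
  '29': 0.001507234726688
  '30': 0.001507234726688
  '31': 0.001507234726688
  '32': 0.004019292604502
  '33': 0.005024115755627
  '34': 0.008038585209003
  '35': 0.012057877813505
  '36': 0.020096463022508
  '37': 0.045217041800643
  '38': 0.130627009646302
  '39': 0.241157556270096
  '40': 0.301446945337621
  '41': 0.160771704180064
  '42': 0.05024115755627
  '43': 0.010048231511254
  '44': 0.002009646302251
group_incidence:
  melanoma: 47.37133239963751
  breast: 32.071274730189366
  thyroid_endocrine: 19.566419904198099
  gynaecological: 13.828898278155048
  lymphohaematopoeitic: 12.799086704249886
  colorectal: 5.149057869525816
  neurological: 3.236550660844799
  bone_connective: 2.795202843456872
  head_neck: 2.059623147810326
  upper_gi: 2.648086904327562
  respiratory: 1.029811573905163
  ill_defined_unknown: 1.618275330422399
  urogenital: 1.176927513034472
capture_prob:
  melanoma: 0.360501567398119
  breast: 0.629107981220657
  thyroid_endocrine: 0.786259541984733
  gynaecological: 0.777777777777778
  lymphohaematopoeitic: 0.720930232558139
  colorectal: 0.642857142857143
  neurological: 0.909090909090909
  bone_connective: 0.888888888888889
  head_neck: 0.692307692307692
  upper_gi: 0.833333333333333
  respiratory: 1.0
  ill_defined_unknown: 0.5
  urogenital: 1.0
extra_admissions_mean:
  melanoma: 0.183098591549296
  breast: 2.230263157894737
  thyroid_endocrine: 0.663865546218487
  gynaecological: 0.987654320987654
  lymphohaematopoeitic: 2.090909090909091
  colorectal: 1.0
  neurological: 1.375
  bone_connective: 1.56
  head_neck: 0.181818181818182
  upper_gi: 1.384615384615385
  respiratory: 0.888888888888889
  ill_defined_unknown: 0.833333333333333
  urogenital: 0.727272727272727
timing_mixture:
  same_month: 0.66
  prior_1_2: 0.28
  prior_3_5: 0.05
  prior_6_plus: 0.01
fp_prevalent_rate: 0.000126519707651
fp_miscode_rate: 3.236550660844799e-05
fp_noise_rate: 8.532724469499924e-05
prevalent_group_probs:
  melanoma: 0.151162790697674
  breast: 0.162790697674419
  thyroid_endocrine: 0.116279069767442
  gynaecological: 0.01421188630491
  lymphohaematopoeitic: 0.441860465116279
  colorectal: 0.01421188630491
  neurological: 0.01421188630491
  bone_connective: 0.01421188630491
  head_neck: 0.01421188630491
  upper_gi: 0.01421188630491
  respiratory: 0.01421188630491
  ill_defined_unknown: 0.01421188630491
  urogenital: 0.01421188630491
miscode_source_probs:
  melanoma: 0.136363636363636
  breast: 0.036363636363636
  thyroid_endocrine: 0.036363636363636
  gynaecological: 0.181818181818182
  lymphohaematopoeitic: 0.036363636363636
  colorectal: 0.318181818181818
  neurological: 0.036363636363636
  bone_connective: 0.036363636363636
  head_neck: 0.036363636363636
  upper_gi: 0.036363636363636
  respiratory: 0.036363636363636
  ill_defined_unknown: 0.036363636363636
  urogenital: 0.036363636363636
miscode_confusion:
  colorectal:
    upper_gi: 1.0
  gynaecological:
    upper_gi: 1.0
  melanoma:
    breast: 0.5
    bone_connective: 0.5
noise_group_probs:
  melanoma: 0.174698795180723
  breast: 0.120481927710843
  thyroid_endocrine: 0.090361445783133
  gynaecological: 0.090361445783133
  lymphohaematopoeitic: 0.289156626506024
  colorectal: 0.066265060240964
  neurological: 0.024096385542169
  bone_connective: 0.042168674698795
  head_neck: 0.012048192771084
  upper_gi: 0.030120481927711
  respiratory: 0.018072289156627
  ill_defined_unknown: 0.024096385542169
  urogenital: 0.018072289156627
linkage_missed_rate: 0.005
linkage_false_rate: 0.003
background_admissions: yes
lookback_start: '1994-01-01'
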