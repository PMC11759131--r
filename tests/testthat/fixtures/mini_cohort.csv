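id,gender,age,income,act_neglect_1,act_neglect_2,act_neglect_3,act_neglect_4,act_neglect_5,act_physical_1,act_physical_2,act_physical_3,act_physical_4,act_physical_5,act_emotional_1,act_emotional_2,act_emotional_3,act_emotional_4,act_emotional_5,act_sexual_1,act_sexual_2,act_sexual_3,act_sexual_4,act_sexual_5,ages_neglect,ages_physical,ages_emotional,ages_sexual,frequency_answer,severity_answer,dis_overweight,dis_diabetes,dis_cancer,dis_hypertension,dis_mi,dis_copd,dis_stroke
1,woman,52,1850.5,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,,8;9;10,,,10-50,seriously,0,0,0,1,0,0,0
2,man,34,3200,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,,,,,NA,NA,0,0,0,0,0,0,0
3,woman,71,990,0,0,0,0,0,NA,0,0,0,0,0,0,0,0,0,0,0,0,0,0,,,,,NA,NA,0,0,1,1,0,0,1
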