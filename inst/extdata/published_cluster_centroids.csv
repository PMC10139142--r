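feature,diverse_common,diverse_bedroom,nonroommate_focused,roommate_focused,restricted
n_partners_roommates_own_bedroom,2.33,2.93,1.36,2.59,0.95
n_partners_nonroommates_other_bedrooms,4.80,4.50,4.27,3.71,2.88
n_partners_roommates_common,0.68,0.08,0.07,0.05,0.01
n_partners_nonroommates_common,1.09,1.21,2.08,0.56,0.32
freq_roommates_own_bedroom,18.60,22.60,11.18,20.00,8.75
freq_nonroommates_other_bedrooms,22.80,27.80,24.36,17.36,8.13
freq_alone,2.00,2.50,1.55,0.50,0.13
freq_roommates_common,11.60,1.50,4.09,1.00,0.63
freq_nonroommates_common,13.40,11.20,14.82,5.36,2.13
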