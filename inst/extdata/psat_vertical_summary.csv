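shark_id,pct_upper_omz,pct_upper_outside,deep_dives_omz,deep_dives_outside,max_depth_omz,max_depth_outside
S1,59.7,69.9,2,6,680,696
S39,98.5,83.8,0,19,288,1464
S47,90.7,74.0,0,29,520,1400
S48,88.8,92.9,2,7,1174,1390
S49,98.6,NA,1,NA,930,NA
S50,NA,85.7,1,2,804,1463
S51,88.4,87.2,0,2,336,712
S52,97.6,89.2,2,24,984,1480
S53,98.0,84.7,3,1,1552,1264
S54,97.9,92.1,0,7,272,1384
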