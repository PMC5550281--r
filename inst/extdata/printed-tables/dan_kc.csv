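pre_dan,compartment,n_post_kc,total_synapses,mean_per_kc,n_sc,pct_sc,n_p,pct_p
PPL1-a3-A,a3,706,1336,1.89,1226,91.8,110,8.2
PPL1-a3-B,a3,786,1646,2.09,1513,91.9,133,8.1
PPL1-ap2a2-A,a2,455,653,1.44,502,76.9,151,23.1
PPL1-ap2a2-B,a2,484,813,1.68,589,72.4,224,27.6
PAM-a1-A,a1,158,182,1.15,164,90.1,18,9.9
PAM-a1-B,a1,121,134,1.11,129,96.3,5,3.7
PAM-a1-C,a1,149,181,1.21,128,70.7,53,29.3
PAM-a1-D,a1,149,170,1.14,159,93.5,11,6.5
PAM-a1-E,a1,163,177,1.09,161,91.0,16,9.0
PAM-a1-F,a1,135,151,1.12,137,90.7,14,9.3
PAM-a1-G,a1,123,138,1.12,120,87.0,18,13.0
PAM-a1-H,a1,95,105,1.11,102,97.1,3,2.9
PAM-a1-I,a1,71,81,1.14,54,66.7,27,33.3
PAM-a1-J,a1,100,112,1.12,107,95.5,5,4.5
PAM-a1-K,a1,40,43,1.07,40,93.0,3,7.0
PAM-a1-L,a1,89,95,1.07,69,72.6,26,27.4
PAM-a1-M,a1,148,179,1.21,166,92.7,13,7.3
PAM-a1-N,a1,78,125,1.60,30,24.0,95,76.0
PAM-a1-O,a1,52,56,1.08,46,82.1,10,17.9
PAM-a1-P,a1,61,82,1.34,19,23.2,63,76.8
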