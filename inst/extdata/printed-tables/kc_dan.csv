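post_dan,compartment,n_pre_kc,total_synapses,mean_per_kc,n_sc,pct_sc,n_p,pct_p
PPL1-a3-A,a3,883,2822,3.20,2706,95.9,116,4.1
PPL1-a3-B,a3,834,2215,2.66,2155,97.3,60,2.7
PPL1-ap2a2-A,a2,488,809,1.66,728,90.0,81,10.0
PPL1-ap2a2-B,a2,480,791,1.65,683,86.3,108,13.7
PAM-a1-A,a1,209,251,1.20,239,95.2,12,4.8
PAM-a1-B,a1,239,332,1.39,320,96.4,12,3.6
PAM-a1-C,a1,218,283,1.30,212,74.9,71,25.1
PAM-a1-D,a1,191,256,1.34,239,93.4,17,6.6
PAM-a1-E,a1,194,254,1.31,248,97.6,6,2.4
PAM-a1-F,a1,193,241,1.25,235,97.5,6,2.5
PAM-a1-G,a1,143,171,1.20,156,91.2,15,8.8
PAM-a1-H,a1,156,176,1.13,170,96.6,6,3.4
PAM-a1-I,a1,156,212,1.36,155,73.1,57,26.9
PAM-a1-J,a1,124,149,1.20,148,99.3,1,0.7
PAM-a1-K,a1,86,97,1.13,87,89.7,10,10.3
PAM-a1-L,a1,174,215,1.24,161,74.9,54,25.1
PAM-a1-M,a1,218,266,1.22,252,94.7,14,5.3
PAM-a1-N,a1,49,59,1.20,26,44.1,33,55.9
PAM-a1-O,a1,50,56,1.12,47,83.9,9,16.1
PAM-a1-P,a1,29,36,1.24,12,33.3,24,66.7
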