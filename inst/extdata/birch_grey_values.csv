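reconstruction,material,mean,sd,units,scale
conventional,air,-0.02,0.28,mu_cm^-1,1
conventional,birch,0.08,0.28,mu_cm^-1,1
conventional,water,0.10,0.28,mu_cm^-1,1
analytical_pr,air,0.81,1.85,delta,1e-7
analytical_pr,birch,4.00,1.65,delta,1e-7
analytical_pr,water,5.14,1.62,delta,1e-7
regularised_pr,air,0.97,0.35,delta,1e-7
regularised_pr,birch,3.98,0.24,delta,1e-7
regularised_pr,water,5.11,0.31,delta,1e-7
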