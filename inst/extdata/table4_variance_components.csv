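diallel,trait,sigma2_P,sigma2_A,sigma2_D,sigma2_e,gca_sca_ratio,baker_ratio,h2,H2
diallel1,hmf,378.44,173.39,62.84,133.68,1.38,0.73,0.46,0.62
diallel1,hf,113.07,52.12,22.41,36.98,1.16,0.70,0.46,0.66
diallel2,hmf,169.53,94.85,27.10,43.89,1.75,0.78,0.56,0.72
diallel2,hf,83.12,33.59,13.66,33.87,1.23,0.71,0.40,0.57
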