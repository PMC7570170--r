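diallel,parent,hmf,hmf_sig,hf,hf_sig
diallel1,CML254,-10.06,**,-4.58,**
diallel1,CML364,13.01,**,8.28,**
diallel1,CML376,-0.30,,-1.45,*
diallel1,CML383,-9.43,**,-4.59,**
diallel1,CML435,9.26,**,6.94,**
diallel1,CML442,9.48,**,1.22,
diallel1,CML484,0.09,,0.58,
diallel1,CML533,-12.05,**,-6.40,**
diallel2,CML364,14.36,**,8.61,**
diallel2,CML381,-3.96,**,-1.97,*
diallel2,CML383,-7.10,**,-3.77,**
diallel2,CML396,2.06,*,3.97,**
diallel2,CML398,-3.89,**,-2.30,**
diallel2,CML451,-0.15,,-1.00,
diallel2,CML510,4.89,**,0.38,
diallel2,CML533,-6.22,**,-3.92,**
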