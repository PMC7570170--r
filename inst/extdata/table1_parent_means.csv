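diallel,line,adaptation,country,doubling_class,hmf,hf
diallel1,CML364,LLT,Colombia,High,74.33,46.05
diallel1,CML435,LLT,Colombia,High,65.30,36.69
diallel1,CML442,ST/MA,Zimbabwe,High,70.90,26.54
diallel1,CML376,ST/MA,Mexico,Medium,30.23,11.76
diallel1,CML484,ST/MA,Mexico,Medium,30.75,11.51
diallel1,CML533,LLT,Colombia,Low,2.44,1.43
diallel1,CML383,ST/MA,Mexico,Low,0.62,0.41
diallel1,CML254,LLT,Mexico,Low,0.15,0.00
diallel2,CML364,LLT,Colombia,High,74.33,46.05
diallel2,CML396,LLT,Mexico,Medium,22.82,21.99
diallel2,CML510,MA,Zimbabwe,Medium,29.87,9.31
diallel2,CML398,LLT,Mexico,Low,7.01,4.24
diallel2,CML451,LLT,Mexico,Low,8.85,4.09
diallel2,CML381,ST/MA,Mexico,Low,3.00,1.78
diallel2,CML533,LLT,Colombia,Low,2.44,1.43
diallel2,CML383,ST,Mexico,Low,0.62,0.41
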