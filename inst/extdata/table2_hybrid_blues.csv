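diallel,group,parent1,parent2,hmf,hf
diallel1,High x High,CML364,CML442,46.83,19.47
diallel1,High x High,CML435,CML364,41.40,27.59
diallel1,High x High,CML435,CML442,33.56,16.31
diallel1,High x Medium,CML364,CML376,42.23,13.74
diallel1,High x Medium,CML442,CML376,41.51,10.86
diallel1,High x Medium,CML435,CML484,38.93,22.03
diallel1,High x Medium,CML435,CML376,38.78,22.69
diallel1,High x Medium,CML442,CML484,33.15,13.67
diallel1,High x Medium,CML364,CML484,31.17,20.82
diallel1,High x Low,CML364,CML254,32.43,15.02
diallel1,High x Low,CML435,CML383,26.22,14.98
diallel1,High x Low,CML364,CML383,24.22,9.91
diallel1,High x Low,CML442,CML383,23.02,5.99
diallel1,High x Low,CML435,CML254,19.06,9.36
diallel1,High x Low,CML364,CML533,17.83,6.54
diallel1,High x Low,CML442,CML254,16.25,3.87
diallel1,High x Low,CML435,CML533,14.74,5.85
diallel1,High x Low,CML442,CML533,11.03,2.55
diallel1,Medium x Medium,CML484,CML376,18.86,9.98
diallel1,Medium x Low,CML376,CML254,11.27,5.81
diallel1,Medium x Low,CML376,CML383,27.62,5.03
diallel1,Medium x Low,CML376,CML533,7.82,3.28
diallel1,Medium x Low,CML484,CML254,12.97,7.71
diallel1,Medium x Low,CML484,CML383,9.32,6.35
diallel1,Medium x Low,CML484,CML533,12.00,5.36
diallel1,Low x Low,CML254,CML383,11.57,4.87
diallel1,Low x Low,CML533,CML254,12.15,4.29
diallel1,Low x Low,CML383,CML533,13.66,4.90
diallel2,High x High,CML364,CML510,37.61,23.83
diallel2,High x Medium,CML364,CML396,17.61,12.82
diallel2,High x Low,CML381,CML364,17.62,9.98
diallel2,High x Low,CML383,CML364,11.64,9.14
diallel2,High x Low,CML398,CML364,18.52,8.18
diallel2,High x Low,CML451,CML364,30.32,16.22
diallel2,High x Low,CML533,CML364,13.03,4.47
diallel2,Medium x Medium,CML396,CML510,16.30,8.72
diallel2,Medium x Low,CML381,CML396,21.29,14.85
diallel2,Medium x Low,CML383,CML396,6.21,3.78
diallel2,Medium x Low,CML398,CML396,8.56,6.20
diallel2,Medium x Low,CML451,CML396,20.19,12.28
diallel2,Medium x Low,CML533,CML396,12.41,9.12
diallel2,Medium x Low,CML533,CML510,11.08,4.90
diallel2,Medium x Low,CML381,CML510,4.00,1.67
diallel2,Medium x Low,CML383,CML510,10.86,7.03
diallel2,Medium x Low,CML398,CML510,14.83,5.62
diallel2,Medium x Low,CML451,CML510,19.19,6.97
diallel2,Low x Low,CML381,CML383,2.00,0.81
diallel2,Low x Low,CML381,CML398,18.12,10.65
diallel2,Low x Low,CML381,CML451,16.81,6.47
diallel2,Low x Low,CML381,CML533,3.03,4.86
diallel2,Low x Low,CML383,CML398,5.59,3.48
diallel2,Low x Low,CML383,CML451,12.26,2.83
diallel2,Low x Low,CML383,CML533,3.98,0.36
diallel2,Low x Low,CML398,CML451,7.01,3.12
diallel2,Low x Low,CML398,CML533,7.27,4.42
diallel2,Low x Low,CML451,CML533,5.60,3.11
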