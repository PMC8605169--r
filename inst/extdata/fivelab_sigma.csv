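lab,analyte,level,sigma
Lab A,K,level1,5.94
Lab A,K,level2,5.97
Lab B,K,level1,7.14
Lab B,K,level2,7.46
Lab C,K,level1,9.84
Lab C,K,level2,10.89
Lab D,K,level1,11.61
Lab D,K,level2,12.60
Lab E,K,level1,10.69
Lab E,K,level2,10.90
Lab A,Na,level1,13.56
Lab A,Na,level2,16.89
Lab B,Na,level1,16.05
Lab B,Na,level2,17.19
Lab C,Na,level1,17.50
Lab C,Na,level2,18.50
Lab D,Na,level1,11.40
Lab D,Na,level2,12.96
Lab E,Na,level1,9.70
Lab E,Na,level2,11.98
Lab A,Cl,level1,11.77
Lab A,Cl,level2,16.43
Lab B,Cl,level1,11.54
Lab B,Cl,level2,14.04
Lab C,Cl,level1,16.31
Lab C,Cl,level2,16.37
Lab D,Cl,level1,9.91
Lab D,Cl,level2,12.03
Lab E,Cl,level1,7.04
Lab E,Cl,level2,6.90
Lab A,Ca,level1,11.23
Lab A,Ca,level2,10.23
Lab B,Ca,level1,8.44
Lab B,Ca,level2,8.58
Lab C,Ca,level1,5.66
Lab C,Ca,level2,5.98
Lab D,Ca,level1,6.03
Lab D,Ca,level2,6.74
Lab E,Ca,level1,9.33
Lab E,Ca,level2,9.86
Lab A,P,level1,5.14
Lab A,P,level2,5.77
Lab B,P,level1,4.77
Lab B,P,level2,4.98
Lab C,P,level1,5.71
Lab C,P,level2,5.73
Lab D,P,level1,5.90
Lab D,P,level2,5.71
Lab E,P,level1,6.16
Lab E,P,level2,8.13
Lab A,GLU,level1,11.14
Lab A,GLU,level2,13.61
Lab B,GLU,level1,6.08
Lab B,GLU,level2,6.95
Lab C,GLU,level1,5.36
Lab C,GLU,level2,5.80
Lab D,GLU,level1,5.72
Lab D,GLU,level2,5.06
Lab E,GLU,level1,5.59
Lab E,GLU,level2,5.95
Lab A,Urea,level1,5.69
Lab A,Urea,level2,5.16
Lab B,Urea,level1,4.09
Lab B,Urea,level2,4.87
Lab C,Urea,level1,7.44
Lab C,Urea,level2,7.04
Lab D,Urea,level1,5.48
Lab D,Urea,level2,5.85
Lab E,Urea,level1,6.21
Lab E,Urea,level2,6.59
Lab A,Crea,level1,6.16
Lab A,Crea,level2,7.78
Lab B,Crea,level1,5.27
Lab B,Crea,level2,5.87
Lab C,Crea,level1,5.24
Lab C,Crea,level2,5.80
Lab D,Crea,level1,6.06
Lab D,Crea,level2,6.39
Lab E,Crea,level1,5.25
Lab E,Crea,level2,5.67
Lab A,TP,level1,10.28
Lab A,TP,level2,17.83
Lab B,TP,level1,5.47
Lab B,TP,level2,5.86
Lab C,TP,level1,5.16
Lab C,TP,level2,5.92
Lab D,TP,level1,9.81
Lab D,TP,level2,11.97
Lab E,TP,level1,5.30
Lab E,TP,level2,5.94
Lab A,mALB,level1,10.63
Lab A,mALB,level2,14.61
Lab B,mALB,level1,7.03
Lab B,mALB,level2,8.40
Lab C,mALB,level1,5.05
Lab C,mALB,level2,5.85
Lab D,mALB,level1,6.16
Lab D,mALB,level2,8.67
Lab E,mALB,level1,5.55
Lab E,mALB,level2,5.83
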