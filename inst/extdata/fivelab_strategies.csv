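lab,analyte,rules,n_controls,run_size
Lab A,K,1_3s/2_2s/R_4s,2,450
Lab B,K,1_3s,2,1000
Lab C,K,1_3s,2,1000
Lab D,K,1_3s,2,1000
Lab E,K,1_3s,2,1000
Lab A,Na,1_3s,2,1000
Lab B,Na,1_3s,2,1000
Lab C,Na,1_3s,2,1000
Lab D,Na,1_3s,2,1000
Lab E,Na,1_3s,2,1000
Lab A,Cl,1_3s,2,1000
Lab B,Cl,1_3s,2,1000
Lab C,Cl,1_3s,2,1000
Lab D,Cl,1_3s,2,1000
Lab E,Cl,1_3s,2,1000
Lab A,Ca,1_3s,2,1000
Lab B,Ca,1_3s,2,1000
Lab C,Ca,1_3s/2_2s/R_4s,2,450
Lab D,Ca,1_3s,2,1000
Lab E,Ca,1_3s,2,1000
Lab A,P,1_3s/2_2s/R_4s,2,450
Lab B,P,1_3s/2_2s/R_4s/4_1s,4,200
Lab C,P,1_3s/2_2s/R_4s,2,450
Lab D,P,1_3s/2_2s/R_4s,2,450
Lab E,P,1_3s,2,1000
Lab A,GLU,1_3s,2,1000
Lab B,GLU,1_3s,2,1000
Lab C,GLU,1_3s/2_2s/R_4s,2,450
Lab D,GLU,1_3s/2_2s/R_4s,2,450
Lab E,GLU,1_3s/2_2s/R_4s,2,450
Lab A,Urea,1_3s/2_2s/R_4s,2,450
Lab B,Urea,1_3s/2_2s/R_4s/4_1s,4,200
Lab C,Urea,1_3s,2,1000
Lab D,Urea,1_3s/2_2s/R_4s,2,450
Lab E,Urea,1_3s,2,1000
Lab A,Crea,1_3s,2,1000
Lab B,Crea,1_3s/2_2s/R_4s,2,450
Lab C,Crea,1_3s/2_2s/R_4s,2,450
Lab D,Crea,1_3s,2,1000
Lab E,Crea,1_3s/2_2s/R_4s,2,450
Lab A,TP,1_3s,2,1000
Lab B,TP,1_3s/2_2s/R_4s,2,450
Lab C,TP,1_3s/2_2s/R_4s,2,450
Lab D,TP,1_3s,2,1000
Lab E,TP,1_3s/2_2s/R_4s,2,450
Lab A,mALB,1_3s,2,1000
Lab B,mALB,1_3s,2,1000
Lab C,mALB,1_3s/2_2s/R_4s,2,450
Lab D,mALB,1_3s,2,1000
Lab E,mALB,1_3s/2_2s/R_4s,2,450
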