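lab,analyte,sigma_level1,sigma_level2,qgi_level1,qgi_level2,improvement
Lab A,K,5.94,5.97,0.85,1.15,Imprecision and trueness
Lab C,Ca,5.66,5.98,1.21,1.47,Trueness
Lab A,P,5.14,5.77,2.61,2.44,Trueness
Lab B,P,4.77,4.98,4.76,3.68,Trueness
Lab C,P,5.71,5.73,1.61,2.22,Trueness
Lab D,P,5.90,5.71,1.79,1.36,Trueness
Lab C,GLU,5.36,5.80,4.46,4.96,Trueness
Lab D,GLU,5.72,5.06,2.25,1.35,Trueness
Lab E,GLU,5.59,5.95,1.73,1.56,Trueness
Lab A,Urea,5.69,5.16,0.23,0.35,Imprecision
Lab B,Urea,4.09,4.87,1.71,1.30,Trueness
Lab D,Urea,5.48,5.85,1.53,1.72,Trueness
Lab B,Crea,5.27,5.87,1.71,3.00,Trueness
Lab C,Crea,5.24,5.80,1.23,1.43,Trueness
Lab E,Crea,5.25,5.67,0.99,0.92,Imprecision and trueness
Lab B,TP,5.47,5.86,2.05,2.60,Trueness
Lab C,TP,5.16,5.92,4.28,4.63,Trueness
Lab E,TP,5.30,5.94,4.40,3.16,Trueness
Lab C,mALB,5.05,5.85,3.15,2.95,Trueness
Lab E,mALB,5.55,5.83,2.08,2.01,Trueness
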