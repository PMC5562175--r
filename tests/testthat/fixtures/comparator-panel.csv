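patient_id,sex,age,height_cm,weight_kg,creatinine_mgdl,quantity,expected
P1,M,60,180,80,1.0,du_bois_bsa,1.996421
P1,M,60,180,80,1.0,cockcroft_gault,88.888889
P1,M,60,180,80,1.0,jelliffe,66.0
P1,M,60,180,80,1.0,wright,96.005227
P1,M,60,180,80,1.0,martin,103.588509
P1,M,60,180,80,1.0,mayo,102.96612
P1,M,60,180,80,1.0,mdrd,76.220772
P1,M,60,180,80,1.0,ckd_epi,81.442898
P1,M,60,180,80,1.0,jelliffe_bsa_adj,76.164039
P1,M,60,180,80,1.0,mayo_bsa_adj,118.822963
P1,M,60,180,80,1.0,mdrd_bsa_adj,87.958816
P1,M,60,180,80,1.0,ckd_epi_bsa_adj,93.985152
P1,M,60,180,80,1.0,calvert_auc5_ckd_epi_adj,594.925759
P2,F,45,162,58,0.7,du_bois_bsa,1.613324
P2,F,45,162,58,0.7,cockcroft_gault,92.926587
P2,F,45,162,58,0.7,jelliffe,100.285714
P2,F,45,162,58,0.7,wright,104.83421
P2,F,45,162,58,0.7,martin,88.751941
P2,F,45,162,58,0.7,mayo,105.153901
P2,F,45,162,58,0.7,mdrd,90.489185
P2,F,45,162,58,0.7,ckd_epi,104.636468
P2,F,45,162,58,0.7,jelliffe_bsa_adj,93.52217
P2,F,45,162,58,0.7,mayo_bsa_adj,98.062033
P2,F,45,162,58,0.7,mdrd_bsa_adj,84.386345
P2,F,45,162,58,0.7,ckd_epi_bsa_adj,97.579497
P2,F,45,162,58,0.7,calvert_auc5_ckd_epi_adj,612.897486
P3,M,75,170,95,2.4,du_bois_bsa,2.060508
P3,M,75,170,95,2.4,cockcroft_gault,35.734954
P3,M,75,170,95,2.4,jelliffe,22.5
P3,M,75,170,95,2.4,wright,35.635154
P3,M,75,170,95,2.4,martin,45.825699
P3,M,75,170,95,2.4,mayo,24.942407
P3,M,75,170,95,2.4,mdrd,26.523867
P3,M,75,170,95,2.4,ckd_epi,25.43411
P3,M,75,170,95,2.4,jelliffe_bsa_adj,26.798516
P3,M,75,170,95,2.4,mayo_bsa_adj,29.707533
P3,M,75,170,95,2.4,mdrd_bsa_adj,31.591123
P3,M,75,170,95,2.4,ckd_epi_bsa_adj,30.293174
P3,M,75,170,95,2.4,calvert_auc5_ckd_epi_adj,276.465868
P4,F,82,155,49,1.6,du_bois_bsa,1.454421
P4,F,82,155,49,1.6,cockcroft_gault,20.969618
P4,F,82,155,49,1.6,jelliffe,27.225
P4,F,82,155,49,1.6,wright,29.068155
P4,F,82,155,49,1.6,martin,25.053851
P4,F,82,155,49,1.6,mayo,36.536938
P4,F,82,155,49,1.6,mdrd,30.859102
P4,F,82,155,49,1.6,ckd_epi,29.699404
P4,F,82,155,49,1.6,jelliffe_bsa_adj,22.888215
P4,F,82,155,49,1.6,mayo_bsa_adj,30.716815
P4,F,82,155,49,1.6,mdrd_bsa_adj,25.943425
P4,F,82,155,49,1.6,ckd_epi_bsa_adj,24.968461
P4,F,82,155,49,1.6,calvert_auc5_ckd_epi_adj,249.842305
P5,M,25,192,105,0.6,du_bois_bsa,2.348363
P5,M,25,192,105,0.6,cockcroft_gault,279.513889
P5,M,25,192,105,0.6,jelliffe,156.666667
P5,M,25,192,105,0.6,wright,248.328329
P5,M,25,192,105,0.6,martin,282.604614
P5,M,25,192,105,0.6,mayo,148.061096
P5,M,25,192,105,0.6,mdrd,164.160885
P5,M,25,192,105,0.6,ckd_epi,139.740995
P5,M,25,192,105,0.6,jelliffe_bsa_adj,212.664827
P5,M,25,192,105,0.6,mayo_bsa_adj,200.983324
P5,M,25,192,105,0.6,mdrd_bsa_adj,222.837741
P5,M,25,192,105,0.6,ckd_epi_bsa_adj,189.689327
P5,M,25,192,105,0.6,calvert_auc5_ckd_epi_adj,1073.446636
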