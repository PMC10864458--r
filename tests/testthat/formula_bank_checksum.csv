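formula_id,n_terms,coef_sum
AB_continuous_memory,5,5.2473065
AB_continuous_time,4,0.6643083000000001
AB_discrete_memory,4,7.12124
AB_discrete_time,6,0.46813999999999995
AB_mixed_memory,6,9.481302
AB_mixed_time,4,-1.3919990000000004
BP_continuous_memory,5,1.6860086
BP_continuous_time,4,-5.10229
BP_discrete_memory,3,4.75574
BP_discrete_time,3,-0.71254
BP_mixed_memory,6,2.0192029999999996
BP_mixed_time,5,-5.423997
C45_continuous_memory,5,4.554204400000001
C45_continuous_time,3,-1.052494
C45_discrete_memory,2,4.5562
C45_discrete_time,4,-0.86997
C45_mixed_memory,5,5.848802
C45_mixed_time,5,-2.482699
LR_continuous_memory,5,1.7050086000000002
LR_continuous_time,5,-2.4350902
LR_discrete_memory,3,4.9066399999999994
LR_discrete_time,4,-1.35893
LR_mixed_memory,5,4.781302999999999
LR_mixed_time,4,-3.966298
NB_continuous_memory,4,4.333
NB_continuous_time,2,-1.5779960000000002
NB_discrete_memory,6,3.1463
NB_discrete_time,4,-1.797782
NB_mixed_memory,3,4.5607995
NB_mixed_time,7,-4.2252980000000004
RF_continuous_memory,5,3.9830058
RF_continuous_time,4,-1.3965903999999998
RF_discrete_memory,3,6.47744
RF_discrete_time,3,-0.07494999999999996
RF_mixed_memory,4,5.755002
RF_mixed_time,5,-3.958698
SVM_continuous_memory,3,4.309008
SVM_continuous_time,5,-6.042789
SVM_discrete_memory,4,4.48664
SVM_discrete_time,4,-0.49850999999999995
SVM_mixed_memory,5,4.141902
SVM_mixed_time,5,-1.7210969999999999
kNN_continuous_memory,5,2.1310087000000006
kNN_continuous_time,5,-5.3384892
kNN_discrete_memory,4,4.90814
kNN_discrete_time,2,-1.06394
kNN_mixed_memory,4,4.5400030000000005
kNN_mixed_time,4,-5.484495
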