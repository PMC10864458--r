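algorithm,category,target,term,coefficient
LR,mixed,time,(Intercept),-0.0034
LR,mixed,time,R_least,-3.948
LR,mixed,time,N,0.000002
LR,mixed,time,Harmean,-0.0149
C45,mixed,time,(Intercept),0.607
C45,mixed,time,N,0.000001
C45,mixed,time,R_least,-2.349
C45,mixed,time,E_C,-0.7297
C45,mixed,time,Harmean,-0.011
SVM,mixed,time,(Intercept),-0.4845
SVM,mixed,time,N,0.000003
SVM,mixed,time,R_least,-2.263
SVM,mixed,time,Harmean,-0.0206
SVM,mixed,time,R_largest,1.047
AB,mixed,time,(Intercept),2.171
AB,mixed,time,N,0.000001
AB,mixed,time,R_least,-2.358
AB,mixed,time,E_C,-1.205
kNN,mixed,time,(Intercept),0.9135
kNN,mixed,time,N,0.000005
kNN,mixed,time,R_least,-4.344
kNN,mixed,time,E_C,-2.054
NB,mixed,time,(Intercept),-0.6855
NB,mixed,time,N,0.000002
NB,mixed,time,R_binary,-0.5441
NB,mixed,time,ME_V,-1.241
NB,mixed,time,R_least,-1.228
NB,mixed,time,E_C,-0.528
NB,mixed,time,P,0.0013
RF,mixed,time,(Intercept),1.395
RF,mixed,time,N,0.000002
RF,mixed,time,R_least,-3.898
RF,mixed,time,E_C,-1.439
RF,mixed,time,Harmean,-0.0167
BP,mixed,time,(Intercept),-4.285
BP,mixed,time,N,0.000003
BP,mixed,time,R_largest,-4.976
BP,mixed,time,E_C,3.845
BP,mixed,time,Harmean,-0.008
LR,discrete,time,(Intercept),-1.419
LR,discrete,time,N,0.00007
LR,discrete,time,N_class,0.0526
LR,discrete,time,ENV,0.0074
C45,discrete,time,(Intercept),-0.8812
C45,discrete,time,N,0.00003
C45,discrete,time,P,0.0015
C45,discrete,time,N_class,0.0097
SVM,discrete,time,(Intercept),-1.359
SVM,discrete,time,N,0.00009
SVM,discrete,time,ENV,0.0087
SVM,discrete,time,E_C,0.8517
AB,discrete,time,(Intercept),0.8643
AB,discrete,time,N,0.00004
AB,discrete,time,ENV,0.003
AB,discrete,time,N_class,0.0183
AB,discrete,time,E_C,-0.4194
AB,discrete,time,P,0.0019
kNN,discrete,time,(Intercept),-1.064
kNN,discrete,time,N,0.00006
NB,discrete,time,(Intercept),-1.983
NB,discrete,time,P,0.0017
NB,discrete,time,R_binary,0.1835
NB,discrete,time,N,0.000018
RF,discrete,time,(Intercept),-1.641
RF,discrete,time,N,0.00005
RF,discrete,time,E_C,1.566
BP,discrete,time,(Intercept),-0.7675
BP,discrete,time,N,0.00006
BP,discrete,time,N_class,0.0549
LR,continuous,time,(Intercept),-0.5703
LR,continuous,time,N,0.000009
LR,continuous,time,R_least,-1.897
LR,continuous,time,N_class,0.0322
LR,continuous,time,Geomean,0.0000008
C45,continuous,time,(Intercept),-0.2581
C45,continuous,time,N,0.000006
C45,continuous,time,R_least,-0.7944
SVM,continuous,time,(Intercept),0.0992
SVM,continuous,time,N,0.00001
SVM,continuous,time,Geomean,0.000001
SVM,continuous,time,MAr,-4.144
SVM,continuous,time,R_least,-1.998
AB,continuous,time,(Intercept),1.221
AB,continuous,time,N,0.000008
AB,continuous,time,Geomean,0.0000003
AB,continuous,time,R_least,-0.5567
kNN,continuous,time,(Intercept),-0.3235
kNN,continuous,time,N,0.00001
kNN,continuous,time,Geomean,0.0000008
kNN,continuous,time,MAr,-3.446
kNN,continuous,time,R_least,-1.569
NB,continuous,time,(Intercept),-1.578
NB,continuous,time,N,0.000004
RF,continuous,time,(Intercept),0.1164
RF,continuous,time,N,0.000009
RF,continuous,time,R_least,-1.513
RF,continuous,time,Geomean,0.0000006
BP,continuous,time,(Intercept),0.7947
BP,continuous,time,N,0.00001
BP,continuous,time,R_least,-2.448
BP,continuous,time,MAr,-3.449
LR,mixed,memory,(Intercept),5.055
LR,mixed,memory,N,0.000003
LR,mixed,memory,R_least,-1.556
LR,mixed,memory,R_largest,0.7283
LR,mixed,memory,R_binary,0.554
C45,mixed,memory,(Intercept),3.354
C45,mixed,memory,P,0.0021
C45,mixed,memory,N,0.000002
C45,mixed,memory,R_largest,1.574
C45,mixed,memory,E_C,0.9187
SVM,mixed,memory,(Intercept),6.427
SVM,mixed,memory,N,0.000002
SVM,mixed,memory,R_least,-2.149
SVM,mixed,memory,Harmean,-0.011
SVM,mixed,memory,Skewness,-0.1251
AB,mixed,memory,(Intercept),6.535
AB,mixed,memory,N,0.000002
AB,mixed,memory,R_binary,2.05
AB,mixed,memory,R_largest,0.5903
AB,mixed,memory,R_discrete,-1.148
AB,mixed,memory,E_C,1.454
kNN,mixed,memory,(Intercept),5.206
kNN,mixed,memory,N,0.000003
kNN,mixed,memory,R_least,-1.84
kNN,mixed,memory,R_largest,1.174
NB,mixed,memory,(Intercept),4.559
NB,mixed,memory,P,0.0018
NB,mixed,memory,N,-0.0000005
RF,mixed,memory,(Intercept),6.851
RF,mixed,memory,N,0.000002
RF,mixed,memory,R_least,-1.088
RF,mixed,memory,Harmean,-0.008
BP,mixed,memory,(Intercept),2.306
BP,mixed,memory,N,0.000003
BP,mixed,memory,R_largest,3.272
BP,mixed,memory,MAr,0.7722
BP,mixed,memory,E_C,2.417
BP,mixed,memory,Harmean,-6.748
LR,discrete,memory,(Intercept),4.872
LR,discrete,memory,N,0.00004
LR,discrete,memory,N_class,0.0346
C45,discrete,memory,(Intercept),4.5535
C45,discrete,memory,P,0.0027
SVM,discrete,memory,(Intercept),5.668
SVM,discrete,memory,N,0.00004
SVM,discrete,memory,N_class,0.0246
SVM,discrete,memory,R_largest,-1.206
AB,discrete,memory,(Intercept),7.115
AB,discrete,memory,N,0.00004
AB,discrete,memory,P,0.0021
AB,discrete,memory,ENV,0.0041
kNN,discrete,memory,(Intercept),4.891
kNN,discrete,memory,N,0.00004
kNN,discrete,memory,N_class,0.0152
kNN,discrete,memory,P,0.0019
NB,discrete,memory,(Intercept),5.1462
NB,discrete,memory,P,0.0018
NB,discrete,memory,ME_V,-1.6206
NB,discrete,memory,R_binary,-0.3956
NB,discrete,memory,N_class,0.0119
NB,discrete,memory,NSR,0.0026
RF,discrete,memory,(Intercept),5.872
RF,discrete,memory,N,0.00004
RF,discrete,memory,E_C,0.6054
BP,discrete,memory,(Intercept),4.715
BP,discrete,memory,N,0.00004
BP,discrete,memory,N_class,0.0407
LR,continuous,memory,(Intercept),5.913
LR,continuous,memory,N,0.000008
LR,continuous,memory,R_least,-1.76
LR,continuous,memory,Geomean,0.0000006
LR,continuous,memory,MAr,-2.448
C45,continuous,memory,(Intercept),4.626
C45,continuous,memory,N,0.000004
C45,continuous,memory,Geomean,0.0000004
C45,continuous,memory,P,0.0036
C45,continuous,memory,Skewness,-0.0754
SVM,continuous,memory,(Intercept),5.996
SVM,continuous,memory,N,0.000008
SVM,continuous,memory,R_least,-1.687
AB,continuous,memory,(Intercept),7.588
AB,continuous,memory,N,0.000006
AB,continuous,memory,Geomean,0.0000005
AB,continuous,memory,MAr,-1.6
AB,continuous,memory,R_least,-0.7407
kNN,continuous,memory,(Intercept),5.916
kNN,continuous,memory,N,0.000008
kNN,continuous,memory,Geomean,0.0000007
kNN,continuous,memory,R_least,-1.515
kNN,continuous,memory,MAr,-2.27
NB,continuous,memory,(Intercept),4.0255
NB,continuous,memory,P,0.0053
NB,continuous,memory,N_class,0.0088
NB,continuous,memory,E_C,0.2934
RF,continuous,memory,(Intercept),6.806
RF,continuous,memory,N,0.000005
RF,continuous,memory,Geomean,0.0000008
RF,continuous,memory,R_least,-1.186
RF,continuous,memory,MAr,-1.637
BP,continuous,memory,(Intercept),5.83
BP,continuous,memory,N,0.000008
BP,continuous,memory,R_least,-1.986
BP,continuous,memory,Geomean,0.0000006
BP,continuous,memory,MAr,-2.158
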